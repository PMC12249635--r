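dos3 <- matrix(c(0, 1, 2,
                 2, 0, 1,
                 1, 2, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("I1", "I2", "I3"), c("s1", "s2", "s3")))

test_that("allele harmonization applies the keep/swap/drop rules", {
  gm <- make_genotypes(dos3, counted = c("C", "C", "A"),
                       other = c("A", "T", "T"))
  ss <- make_sumstats(c("s1", "s2", "s3"), beta = c(0.5, -1, 2),
                      effect = c("C", "T", "A"),
                      other = c("A", "C", "T"))
  h <- harmonize(gm, ss, drop_palindromic = TRUE)
  # s1: counted == effect -> kept as-is
  expect_equal(unname(h$dosages[, "s1"]), c(0, 2, 1))
  # s2: counted C vs sumstats (T, C) -> swapped, g -> 2 - g
  expect_equal(unname(h$dosages[, "s2"]), c(1, 2, 0))
  # s3: A/T palindromic -> dropped
  expect_false("s3" %in% colnames(h$dosages))
  expect_equal(unname(h$dropped["palindromic"]), 1L)

  h2 <- harmonize(gm, ss, drop_palindromic = FALSE)
  expect_true("s3" %in% colnames(h2$dosages))

  # mismatching allele pair is dropped with its own reason
  ss_mm <- make_sumstats("s1", beta = 0.5, effect = "G", other = "T")
  h3 <- harmonize(gm, ss_mm, snp_ids = "s1")
  expect_equal(unname(h3$dropped["allele_mismatch"]), 1L)
  expect_equal(ncol(h3$dosages), 0L)
})

map_for <- function(genes, snps) {
  structure(list(gene_to_snps = stats::setNames(snps, genes),
                 snp_to_genes = list(), window_bp = 20000),
            class = "snp_gene_map")
}

test_that("the module score is the hand-computed weighted dosage sum", {
  gm <- make_genotypes(dos3, counted = c("C", "C", "C"),
                       other = c("A", "A", "A"))
  ss <- make_sumstats(c("s1", "s2", "s3"), beta = c(0.5, -1, 2))
  map <- map_for("G1", list(c("s1", "s2", "s3")))
  prof <- compute_mprs(gm, ss, "G1", map)
  # I1: 0*0.5 + 1*(-1) + 2*2 = 3
  expect_equal(prof$score[prof$individual_id == "I1"], 3)
  expect_equal(attr(prof, "n_snps_used"), 3L)

  zero <- gm
  zero$dosages[] <- 0
  expect_equal(compute_mprs(zero, ss, "G1", map)$score, rep(0, 3))
})

test_that("a SNP shared by two module genes counts once (dedup)", {
  gm <- make_genotypes(dos3[, "s1", drop = FALSE], counted = "C",
                       other = "A")
  ss <- make_sumstats("s1", beta = 1)
  map <- map_for(c("G1", "G2"), list("s1", "s1"))
  prof <- compute_mprs(gm, ss, c("G1", "G2"), map)
  expect_equal(prof$score, unname(dos3[, "s1"]))      # once, not twice
  lit <- compute_mprs(gm, ss, c("G1", "G2"), map, dedup = FALSE)
  expect_equal(lit$score, 2 * unname(dos3[, "s1"]))   # literal double count
})

test_that("scores are additive over modules with disjoint SNP sets", {
  set.seed(7)
  n_ind <- 20
  dos <- matrix(rbinom(n_ind * 6, 2, 0.3), n_ind,
                dimnames = list(sprintf("I%02d", 1:n_ind),
                                sprintf("s%d", 1:6)))
  gm <- make_genotypes(dos, counted = rep("C", 6), other = rep("A", 6))
  ss <- make_sumstats(sprintf("s%d", 1:6), beta = rnorm(6))
  map <- map_for(c("GA", "GB"), list(sprintf("s%d", 1:3),
                                     sprintf("s%d", 4:6)))
  pa <- compute_mprs(gm, ss, "GA", map)
  pb <- compute_mprs(gm, ss, "GB", map)
  pu <- compute_mprs(gm, ss, c("GA", "GB"), map)
  expect_equal(pa$score + pb$score, pu$score, tolerance = 1e-12)
})

test_that("scores are invariant under allele-swap re-encoding", {
  set.seed(8)
  n_ind <- 15
  dos <- matrix(rbinom(n_ind * 4, 2, 0.4), n_ind,
                dimnames = list(sprintf("I%02d", 1:n_ind),
                                sprintf("s%d", 1:4)))
  gm <- make_genotypes(dos, counted = rep("C", 4), other = rep("A", 4))
  flipped <- make_genotypes(2 - dos, counted = rep("A", 4),
                            other = rep("C", 4))
  ss <- make_sumstats(sprintf("s%d", 1:4), beta = rnorm(4))
  map <- map_for("G1", list(sprintf("s%d", 1:4)))
  p1 <- compute_mprs(gm, ss, "G1", map)
  p2 <- compute_mprs(flipped, ss, "G1", map)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
})

test_that("missing dosages follow the configured policy", {
  dos <- dos3
  dos["I2", "s2"] <- NA
  gm <- make_genotypes(dos, counted = rep("C", 3), other = rep("A", 3))
  ss <- make_sumstats(c("s1", "s2", "s3"), beta = c(1, 1, 1))
  map <- map_for("G1", list(c("s1", "s2", "s3")))
  imp <- compute_mprs(gm, ss, "G1", map, missing_policy = "mean_impute")
  # imputed value = mean of the observed dosages at s2 -> (1 + 2) / 2
  expect_equal(imp$score[2], 2 + 1.5 + 1)
  zer <- compute_mprs(gm, ss, "G1", map, missing_policy = "zero")
  expect_equal(zer$score[2], 3)
  drp <- compute_mprs(gm, ss, "G1", map, missing_policy = "drop_individual")
  expect_true(is.na(drp$score[2]))
  expect_false(anyNA(drp$score[-2]))

  # mean imputation keeps the population mean score unchanged in expectation
  set.seed(9)
  n_ind <- 600
  full <- matrix(rbinom(n_ind * 3, 2, 0.4), n_ind,
                 dimnames = list(sprintf("I%03d", 1:n_ind),
                                 c("s1", "s2", "s3")))
  holey <- full
  holey[cbind(sample(n_ind, 150), sample(3, 150, TRUE))] <- NA
  ssb <- make_sumstats(c("s1", "s2", "s3"), beta = c(0.5, 1, -0.3))
  p_full <- compute_mprs(make_genotypes(full, rep("C", 3), rep("A", 3)),
                         ssb, "G1", map)
  p_imp <- compute_mprs(make_genotypes(holey, rep("C", 3), rep("A", 3)),
                        ssb, "G1", map)
  mc_se <- sd(p_full$score) / sqrt(n_ind)
  expect_lt(abs(mean(p_imp$score) - mean(p_full$score)), 3 * mc_se)
})

test_that("a module with no usable SNPs is a named error", {
  gm <- make_genotypes(dos3, counted = rep("C", 3), other = rep("A", 3))
  ss <- make_sumstats("sX", beta = 1)
  map <- map_for("G1", list("s1"))
  expect_error(compute_mprs(gm, ss, "G1", map, module_id = "left.M9"),
               "left.M9")
})
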
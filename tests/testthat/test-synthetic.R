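test_that("simulation is fully deterministic under its seed", {
  cfg <- simulation_config(seed = 101, n_individuals = 60)
  a <- simulate_dataset(cfg, n_truth_draws = 1e3)
  b <- simulate_dataset(cfg, n_truth_draws = 1e3)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$scores, b$scores)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$expression, b$expression)
  c_ <- simulate_dataset(simulation_config(seed = 102, n_individuals = 60),
                         n_truth_draws = 1e3)
  expect_false(identical(a$scores, c_$scores))
})

test_that("planted cliques and bare scaffolds appear as configured", {
  cfg <- simulation_config(seed = 5, n_genes = 20, edge_density = 0,
                           planted_modules = list(list(size = 5, p_in = 1,
                                                       score_alpha = 0.5)))
  net <- generate_network(cfg)
  members <- net$membership[[1]]
  expect_equal(length(members), 5L)
  inside <- net$edges$from %in% members & net$edges$to %in% members
  expect_equal(sum(inside), choose(5, 2))  # a full 5-clique

  cfg0 <- simulation_config(seed = 5, n_genes = 20, edge_density = 0,
                            planted_modules = list(list(size = 5, p_in = 0,
                                                        score_alpha = 0.5)))
  net0 <- generate_network(cfg0)
  expect_equal(nrow(net0$edges), 19L)  # spanning scaffold only
})

test_that("gene scores separate planted from background only when alpha < 1", {
  cfg <- simulation_config(seed = 6, n_genes = 200,
                           planted_modules = list(list(size = 10,
                                                       p_in = 0.9,
                                                       score_alpha = 0.01)))
  net <- generate_network(cfg)
  sc <- generate_gene_scores(net, cfg)
  expect_true(all(sc$p_value > 0 & sc$p_value <= 1))
  w <- -log10(sc$p_value)
  names(w) <- sc$gene_id
  planted <- net$membership[[1]]
  bg <- setdiff(sc$gene_id, planted)
  # Beta(0.01, 1): E[-log10 p] = 1/(0.01 ln 10) ~ 43 vs uniform ~ 0.43
  expect_gt(mean(w[planted]), 10 * mean(w[bg]))

  cfg_null <- simulation_config(seed = 6, n_genes = 200,
                                planted_modules = list(list(size = 10,
                                                            p_in = 0.9,
                                                            score_alpha = 1)))
  net_null <- generate_network(cfg_null)
  sc_null <- generate_gene_scores(net_null, cfg_null)
  w0 <- -log10(sc_null$p_value)
  names(w0) <- sc_null$gene_id
  # alpha = 1 is Uniform(0,1): planted indistinguishable from background
  expect_gt(suppressWarnings(stats::ks.test(
    sc_null$p_value[sc_null$gene_id %in% net_null$membership[[1]]],
    "punif"))$p.value, 0.01)
})

test_that("genotype generation places the window-boundary SNP", {
  cfg <- simulation_config(seed = 7, n_genes = 12, n_individuals = 40)
  net <- generate_network(cfg)
  geno <- generate_genotypes_and_sumstats(cfg, net)
  ann1 <- geno$annotation[1, ]
  expect_true((ann1$start - 20000) %in%
                geno$sumstats$meta1$pos[geno$sumstats$meta1$chrom ==
                                          ann1$chrom])
  expect_true(all(geno$genotypes$dosages %in% 0:2))
  expect_equal(nrow(geno$sumstats$meta1), length(geno$genotypes$snp_ids))
})

test_that("a zero effect-size target yields near-zero realized d", {
  cfg <- simulation_config(seed = 8, n_individuals = 4000,
                           target_cohens_d = 0)
  net <- generate_network(cfg)
  geno <- generate_genotypes_and_sumstats(cfg, net)
  x <- geno$mprs_true[, 1]
  g <- geno$group[rownames(geno$mprs_true)]
  d <- cohens_d_ci(x[g == 1], x[g == 0])$d
  expect_lt(abs(d), 0.1)
})

test_that("the analytic d calibration is unbiased over replicates", {
  # mean realized d across replicates within +/-0.05 of the 0.5 target
  ds <- sapply(1:60, function(seed) {
    cfg <- simulation_config(seed = seed, n_genes = 30, n_individuals = 4000,
                             target_cohens_d = 0.5)
    net <- generate_network(cfg)
    geno <- generate_genotypes_and_sumstats(cfg, net)
    x <- geno$mprs_true[, 1]
    g <- geno$group[rownames(geno$mprs_true)]
    cohens_d_ci(x[g == 1], x[g == 0])$d
  })
  expect_lt(abs(mean(ds) - 0.5), 0.05)
})

test_that("phenotype generation honours the mediation and survival nulls", {
  cfg <- simulation_config(seed = 9, n_individuals = 300,
                           mediation = list(a = 0, b = 0.5, c = 0.7,
                                            gamma = c(0, 0, 0)))
  truth <- true_mediation_effects(0, 0.5, 0.7, n_draws = 2e5, seed = 1)
  expect_equal(truth$acme, 0, tolerance = 1e-3)  # a = 0 kills the path

  net <- generate_network(cfg)
  geno <- generate_genotypes_and_sumstats(cfg, net)
  ph <- generate_phenotypes(geno$mprs_true, cfg)
  expect_true(all(ph$diagnosis %in% c("CN", "SMC", "EMCI", "LMCI", "AD")))
  mci <- ph$diagnosis %in% c("EMCI", "LMCI")
  expect_true(all(!is.na(ph$conv_months[mci])))
  expect_true(all(is.na(ph$conv_months[!mci])))

  cfg0 <- simulation_config(seed = 10, n_individuals = 300,
                            surv = list(base_hazard = 0.02,
                                        log_hr_per_sd = log(1.3),
                                        censor_rate = 0))
  net0 <- generate_network(cfg0)
  geno0 <- generate_genotypes_and_sumstats(cfg0, net0)
  ph0 <- generate_phenotypes(geno0$mprs_true, cfg0)
  mci0 <- ph0$diagnosis %in% c("EMCI", "LMCI")
  expect_true(all(ph0$conv_event[mci0] == 1))  # no censoring -> all events
})

test_that("expression plants correlation only in the target tissue", {
  cfg <- simulation_config(seed = 11,
                           expression = list(n_samples = 200, rho = 0.6,
                                             tissues = c("amygdala",
                                                         "cortex"),
                                             target_tissue = "amygdala"))
  net <- generate_network(cfg)
  expr <- generate_expression(net, cfg)
  members <- net$membership[[1]]
  pcc_t <- module_coexpression(expr$amygdala, members)
  pcc_o <- module_coexpression(expr$cortex, members)
  expect_gt(pcc_t, 0.4)
  expect_lt(abs(pcc_o), 0.15)

  cfg0 <- simulation_config(seed = 11,
                            expression = list(n_samples = 200, rho = 0,
                                              tissues = "amygdala",
                                              target_tissue = "amygdala"))
  expr0 <- generate_expression(net, cfg0)
  expect_lt(abs(module_coexpression(expr0$amygdala, members)), 0.15)
})

test_that("simulate_dataset writes a readable, consistent bundle", {
  out <- file.path(tempdir(), "simbundle")
  cfg <- simulation_config(seed = 12, n_individuals = 50,
                           expression = list(n_samples = 10, rho = 0.6,
                                             tissues = "amygdala",
                                             target_tissue = "amygdala"))
  suppressMessages(sim <- simulate_dataset(cfg, out_dir = out,
                                           n_truth_draws = 1e3))
  suppressMessages({
    edges <- read_edge_list(file.path(out, "ppi_edges.tsv"))
    scores <- read_gene_scores(file.path(out, "gene_scores.tsv"))
    geno <- read_genotypes(file.path(out, "genotypes.tsv"))
    ss <- read_sumstats(file.path(out, "sumstats_meta1.tsv"))
    ph <- read_phenotypes(file.path(out, "phenotypes.tsv"))
    gmt <- read_gmt(file.path(out, "gene_sets.gmt"))
  })
  expect_equal(nrow(edges), nrow(sim$network$edges))
  expect_equal(scores$p_value, sim$scores$p_value)
  expect_equal(dim(geno$dosages), dim(sim$genotypes$dosages))
  expect_equal(ss$beta, sim$sumstats$meta1$beta)
  expect_equal(nrow(ph), 50L)
  expect_setequal(gmt$PLANTED1, sim$network$membership[[1]])
  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"))
  expect_equal(unlist(truth$planted_modules[[1]]),
               sim$network$membership[[1]])
})
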
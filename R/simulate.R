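#' Simulation configuration with known ground truth
#'
#' Bundles every parameter of the synthetic cohort: a random interaction
#' network with planted high-scoring modules, per-gene association scores,
#' LD-free genotypes whose planted-module risk score separates synthetic
#' cases from controls by a target Cohen's d, phenotypes from an explicit
#' mediation + survival model, and tissue expression with planted
#' within-module correlation. Defaults describe a compact cohort that every
#' pipeline stage can recover structure from: a 100-gene network of
#' background density 0.085 with one 10-gene planted module (within-module
#' edge probability 0.9, score shape alpha = 0.01; module-external edge
#' probability reduced so module degrees match the background),
#' 400 individuals, 3 SNPs per gene with minor allele
#' frequencies in [0.2, 0.5], a case-control score separation of d = 0.5,
#' mediation paths (a = 0.4, b = 0.5, c = 0.67) giving a mediated
#' proportion near 0.22, a conversion hazard ratio of 1.3 per SD of the
#' risk score with 40% censoring, and within-module expression correlation
#' 0.6 in the target tissue only.
#'
#' @param n_genes Number of genes (network nodes).
#' @param edge_density Background edge probability.
#' @param planted_modules List of `list(size, p_in, score_alpha)`: module
#'   size (>= 3), within-module edge probability, and the Beta(alpha, 1)
#'   shape for member gene p-values (alpha = 1 is the null; alpha << 1
#'   concentrates p near 0).
#' @param n_individuals Cohort size (split 1:1 into synthetic case/control
#'   groups for genotype calibration).
#' @param n_snps_per_gene SNPs placed inside each gene body.
#' @param maf_range Range minor allele frequencies are drawn from.
#' @param target_cohens_d Target standardized case-control difference of
#'   the planted-module risk score (recycled over planted modules).
#' @param mediation List `a` (exposure -> mediator), `b` (mediator ->
#'   outcome, latent logit scale), `c` (direct exposure -> outcome), and
#'   `gamma` (covariate effects on the outcome, order age/sex/education).
#' @param surv List `base_hazard` (events per month at x = 0),
#'   `log_hr_per_sd` (true log hazard ratio per SD of the score), and
#'   `censor_rate` (administrative censoring fraction).
#' @param expression List `n_samples`, `rho` (within-module correlation in
#'   the target tissue), `tissues`, `target_tissue`.
#' @param seed Mandatory integer seed; all generators derive per-stage
#'   streams from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 100,
                              edge_density = 0.085,
                              planted_modules = list(
                                list(size = 10, p_in = 0.9, score_alpha = 0.01)
                              ),
                              n_individuals = 400,
                              n_snps_per_gene = 3,
                              maf_range = c(0.2, 0.5),
                              target_cohens_d = 0.5,
                              mediation = list(a = 0.4, b = 0.5, c = 0.67,
                                               gamma = c(age = 0, sex = 0,
                                                         education = 0)),
                              surv = list(base_hazard = 0.02,
                                          log_hr_per_sd = log(1.3),
                                          censor_rate = 0.4),
                              expression = list(n_samples = 80, rho = 0.6,
                                                tissues = c("amygdala",
                                                            "cortex",
                                                            "blood"),
                                                target_tissue = "amygdala"),
                              seed) {
  assert_that(!missing(seed), "a seed is mandatory for reproducible simulation")
  assert_that(edge_density >= 0 && edge_density <= 1,
              "edge_density must be a probability")
  sizes <- vapply(planted_modules, `[[`, 0, "size")
  assert_that(all(sizes >= 3), "planted module sizes must be >= 3")
  assert_that(sum(sizes) <= n_genes,
              "planted module sizes exceed the number of genes")
  assert_that(all(vapply(planted_modules, `[[`, 0, "p_in") >= 0 &
                    vapply(planted_modules, `[[`, 0, "p_in") <= 1),
              "within-module edge probabilities must lie in [0, 1]")
  assert_that(all(maf_range > 0 & maf_range < 1) && maf_range[1] <= maf_range[2],
              "maf_range must be an increasing pair inside (0, 1)")
  assert_that(surv$censor_rate >= 0 && surv$censor_rate < 1,
              "censor_rate must lie in [0, 1)")
  assert_that(expression$rho >= 0 && expression$rho <= 1,
              "expression rho must lie in [0, 1]")
  cfg <- list(n_genes = n_genes, edge_density = edge_density,
              planted_modules = planted_modules,
              n_individuals = n_individuals,
              n_snps_per_gene = n_snps_per_gene, maf_range = maf_range,
              target_cohens_d = rep_len(target_cohens_d, length(planted_modules)),
              mediation = mediation, surv = surv, expression = expression,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a random network with planted, degree-balanced modules
#'
#' Background pairs are connected with probability `edge_density`; pairs
#' inside planted module k with probability `p_in`. The probability of an
#' edge between a module node and the rest is reduced to
#' `max(0, (edge_density * (n - 1) - p_in * (size - 1)) / (n - size))`
#' so the expected total degree of module nodes matches the background: a
#' degree-balanced planted-partition design. Without the balance the
#' module would be both the densest and the highest-degree region, which
#' confounds degree-aware permutation nulls at desk scale. A random
#' spanning scaffold (a chain over a shuffled node order) guarantees
#' connectivity, so propagation never sees a zero-degree node.
#'
#' @param config A [simulation_config()].
#' @return List with `edges` (data.frame from/to), `genes`, and
#'   `membership` (list of planted-module gene vectors).
#' @export
generate_network <- function(config) {
  set.seed(derive_seed(config$seed, "network"))
  n <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  planted <- list()
  used <- 0L
  pool <- sample(genes)  # random placement of planted modules
  for (k in seq_along(config$planted_modules)) {
    size <- config$planted_modules[[k]]$size
    planted[[k]] <- sort(pool[(used + 1L):(used + size)])
    used <- used + size
  }
  pairs <- utils::combn(genes, 2L)
  a <- pairs[1L, ]; b <- pairs[2L, ]
  p_edge <- rep(config$edge_density, length(a))
  for (k in seq_along(planted)) {
    size <- config$planted_modules[[k]]$size
    p_in <- config$planted_modules[[k]]$p_in
    p_ext <- max(0, (config$edge_density * (n - 1) - p_in * (size - 1)) /
                   (n - size))
    am <- a %in% planted[[k]]; bm <- b %in% planted[[k]]
    p_edge[am & bm] <- p_in
    p_edge[xor(am, bm)] <- pmin(p_edge[xor(am, bm)], p_ext)
  }
  keep <- stats::runif(length(a)) < p_edge
  ord <- sample(genes)  # spanning scaffold
  sa <- c(a[keep], ord[-n])
  sb <- c(b[keep], ord[-1L])
  from <- pmin(sa, sb)
  to <- pmax(sa, sb)
  dup <- duplicated(paste(from, to, sep = "\r"))
  list(edges = data.frame(from = from[!dup], to = to[!dup],
                          stringsAsFactors = FALSE),
       genes = genes, membership = planted)
}

#' Generate gene-level association p-values
#'
#' Background genes draw p ~ Uniform(0, 1); genes of planted module k draw
#' p ~ Beta(alpha_k, 1), so `alpha = 1` is an exact null and small alpha
#' concentrates signal on the module.
#'
#' @param network Output of [generate_network()].
#' @param config A [simulation_config()].
#' @return A gene score data.frame (`gene_id`, `p_value`).
#' @export
generate_gene_scores <- function(network, config) {
  set.seed(derive_seed(config$seed, "gene_scores"))
  p <- stats::runif(length(network$genes))
  names(p) <- network$genes
  for (k in seq_along(network$membership)) {
    members <- network$membership[[k]]
    alpha <- config$planted_modules[[k]]$score_alpha
    p[members] <- stats::rbeta(length(members), alpha, 1)
  }
  p <- pmax(p, 1e-300)  # keep scores in (0, 1]
  data.frame(gene_id = network$genes, p_value = unname(p[network$genes]),
             stringsAsFactors = FALSE)
}

# Genes laid out on one chromosome, 10 kb bodies spaced 200 kb apart so the
# +/-20 kb windows of adjacent genes never overlap by construction.
default_annotation <- function(genes) {
  start <- 100000L + (seq_along(genes) - 1L) * 200000L
  data.frame(gene_id = genes, chrom = "1", start = start,
             end = start + 10000L, stringsAsFactors = FALSE)
}

#' Generate genotypes, disease summary statistics and gene annotation
#'
#' SNPs are LD-free: `n_snps_per_gene` per gene body plus one SNP placed at
#' the exact lower window boundary (start - 20000) of the first gene, so
#' window mapping is exercised at its edge. Dosages are Binomial(2, MAF).
#' Individuals are split into synthetic case and control groups; for SNPs
#' of planted module k, group allele frequencies are shifted by +/- delta
#' with delta calibrated analytically so the case-control difference of the
#' module risk score (sum of beta x dosage) has standardized effect size
#' `target_cohens_d[k]`:
#' delta = d * sd(score) / (4 * sum(|beta|)), where
#' sd(score)^2 = sum(beta^2 * 2 * MAF * (1 - MAF)).
#'
#' Two summary-statistic tables are produced (labels `meta1`, `meta2`);
#' `meta2` carries attenuated, noisier copies of the `meta1` effect sizes,
#' mimicking a second, partially concordant meta-analysis. About 20% of
#' background SNPs are stored on the opposite allele encoding (dosage
#' 2 - g), and two background SNPs are strand-palindromic, so allele
#' harmonization has real work to do.
#'
#' @param config A [simulation_config()].
#' @param network Output of [generate_network()].
#' @param annotation Optional gene annotation; defaults to an even layout
#'   on one chromosome.
#' @return List with `genotypes` (genotype_matrix), `sumstats` (list of two
#'   data.frames), `annotation`, `group` (named 0/1 vector; 1 = case),
#'   `mprs_true` (individuals x planted modules matrix of true module
#'   scores on the effect-allele scale), `module_snps` (list), and `delta`.
#' @export
generate_genotypes_and_sumstats <- function(config, network,
                                            annotation = NULL) {
  set.seed(derive_seed(config$seed, "genotypes"))
  genes <- network$genes
  if (is.null(annotation)) annotation <- default_annotation(genes)
  n_ind <- config$n_individuals
  individuals <- sprintf("I%05d", seq_len(n_ind))
  group <- stats::setNames(rep(c(0L, 1L), length.out = n_ind), individuals)

  snp_tab <- do.call(rbind, lapply(seq_along(genes), function(i) {
    ann <- annotation[annotation$gene_id == genes[i], ]
    pos <- round(seq(ann$start, ann$end, length.out = config$n_snps_per_gene + 2L))
    pos <- pos[2:(config$n_snps_per_gene + 1L)]
    data.frame(gene_id = genes[i], chrom = ann$chrom, pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }))
  # boundary SNP at the exact lower edge of gene 1's window
  ann1 <- annotation[annotation$gene_id == genes[1L], ]
  snp_tab <- rbind(snp_tab,
                   data.frame(gene_id = genes[1L], chrom = ann1$chrom,
                              pos = ann1$start - 20000L,
                              stringsAsFactors = FALSE))
  snp_tab <- snp_tab[order(snp_tab$pos), ]
  n_snp <- nrow(snp_tab)
  snp_tab$snp_id <- sprintf("rs%05d", seq_len(n_snp))

  planted_genes <- unlist(network$membership)
  module_of_gene <- integer(0)
  for (k in seq_along(network$membership)) {
    module_of_gene[network$membership[[k]]] <- k
  }
  snp_module <- ifelse(snp_tab$gene_id %in% planted_genes,
                       module_of_gene[snp_tab$gene_id], 0L)

  # alleles: non-palindromic pairs everywhere, except two deliberate
  # palindromic background SNPs (dropped later by harmonization)
  pair_pool <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
  picks <- sample(length(pair_pool), n_snp, replace = TRUE)
  effect <- vapply(pair_pool[picks], `[[`, "", 1L)
  other <- vapply(pair_pool[picks], `[[`, "", 2L)
  bg_idx <- which(snp_module == 0L)
  if (length(bg_idx) >= 2L) {
    pal <- bg_idx[1:2]
    effect[pal] <- c("A", "C")
    other[pal] <- c("T", "G")
  }

  maf <- stats::runif(n_snp, config$maf_range[1], config$maf_range[2])
  beta <- stats::rnorm(n_snp, 0, 0.05)
  delta <- rep(0, n_snp)
  for (k in seq_along(network$membership)) {
    idx <- which(snp_module == k)
    beta[idx] <- 0.1 * sample(c(-1, 1), length(idx), replace = TRUE)
    sd_score <- sqrt(sum(beta[idx]^2 * 2 * maf[idx] * (1 - maf[idx])))
    d_target <- config$target_cohens_d[k]
    delta_k <- d_target * sd_score / (4 * sum(abs(beta[idx])))
    delta[idx] <- delta_k * sign(beta[idx])
  }
  maf_case <- pmin(pmax(maf + delta, 0.01), 0.99)
  maf_ctrl <- pmin(pmax(maf - delta, 0.01), 0.99)

  dos <- matrix(NA_real_, n_ind, n_snp, dimnames = list(individuals,
                                                        snp_tab$snp_id))
  is_case <- group == 1L
  for (j in seq_len(n_snp)) {
    p_ind <- ifelse(is_case, maf_case[j], maf_ctrl[j])
    dos[, j] <- stats::rbinom(n_ind, 2L, p_ind)
  }

  # true module scores on the effect-allele scale, before any re-encoding
  mprs_true <- matrix(0, n_ind, length(network$membership),
                      dimnames = list(individuals,
                                      paste0("planted", seq_along(network$membership))))
  module_snps <- list()
  for (k in seq_along(network$membership)) {
    idx <- which(snp_module == k)
    module_snps[[k]] <- snp_tab$snp_id[idx]
    mprs_true[, k] <- dos[, idx, drop = FALSE] %*% beta[idx]
  }

  # re-encode ~20% of background SNPs on the opposite allele
  counted <- effect
  counted_other <- other
  flip <- bg_idx[stats::runif(length(bg_idx)) < 0.2]
  if (length(flip) > 0L) {
    dos[, flip] <- 2 - dos[, flip]
    counted[flip] <- other[flip]
    counted_other[flip] <- effect[flip]
  }

  se <- stats::runif(n_snp, 0.01, 0.03)
  p_meta1 <- 2 * stats::pnorm(-abs(beta) / se)
  beta2 <- 0.8 * beta + stats::rnorm(n_snp, 0, 0.02)
  p_meta2 <- 2 * stats::pnorm(-abs(beta2) / se)
  make_ss <- function(b, p) {
    data.frame(snp_id = snp_tab$snp_id, chrom = snp_tab$chrom,
               pos = snp_tab$pos, effect_allele = effect,
               other_allele = other, beta = b,
               p_value = pmax(p, 1e-300), stringsAsFactors = FALSE)
  }
  list(genotypes = new_genotype_matrix(dos, counted, counted_other),
       sumstats = list(meta1 = make_ss(beta, p_meta1),
                       meta2 = make_ss(beta2, p_meta2)),
       annotation = annotation, group = group, mprs_true = mprs_true,
       module_snps = module_snps, delta = delta)
}

#' Generate conversion times from a proportional-hazards model
#'
#' Event times are Exponential with log hazard `log_hr_per_sd * x_std`
#' around `base_hazard`; administrative censoring at the empirical
#' (1 - censor_rate) quantile of the drawn times yields the configured
#' censoring fraction. Times are then rounded up to whole months, matching
#' visit-schedule granularity (and guaranteeing ties, which is why the Cox
#' fit defaults to the Efron approximation).
#'
#' @param x_std Standardized exposure (one value per individual).
#' @param surv List with `base_hazard`, `log_hr_per_sd`, `censor_rate`.
#' @param seed Integer seed.
#' @return data.frame with `conv_months` and `conv_event`.
#' @export
generate_survival_times <- function(x_std, surv, seed) {
  set.seed(seed)
  n <- length(x_std)
  rate <- surv$base_hazard * exp(surv$log_hr_per_sd * x_std)
  t_event <- stats::rexp(n, rate)
  cutoff <- stats::quantile(t_event, 1 - surv$censor_rate, names = FALSE)
  event <- as.integer(t_event <= cutoff)
  months <- ceiling(pmin(t_event, cutoff))
  data.frame(conv_months = months, conv_event = event)
}

#' Generate phenotypes from an explicit mediation + survival model
#'
#' The exposure x is the true planted-module risk score (first planted
#' module), standardized. The mediator is m = a * x_std + N(0, 1); the
#' binary outcome is y ~ Bernoulli(logistic(c * x_std + b * m + gamma' z))
#' with covariates z = (age, sex, education). Diagnosis is assigned from y:
#' y = 0 individuals are CN/SMC (80/20 at random), y = 1 individuals are
#' EMCI/LMCI/AD by ascending terciles of the latent score. The left
#' amygdala grey-matter density is an affine image of the mediator
#' (lower density = worse), keeping mediation effects invariant to the
#' re-scaling; the right side adds small independent noise. Conversion
#' times are generated for the MCI (EMCI + LMCI) subset only, with the
#' exposure re-standardized within that subset so the configured hazard
#' ratio is per SD in the analysis cohort.
#'
#' @param mprs_true Matrix of true module scores (individuals x modules)
#'   from [generate_genotypes_and_sumstats()].
#' @param config A [simulation_config()].
#' @return A phenotype data.frame (see [read_phenotypes()] for columns).
#' @export
generate_phenotypes <- function(mprs_true, config) {
  set.seed(derive_seed(config$seed, "phenotypes"))
  med <- config$mediation
  ids <- rownames(mprs_true)
  n <- length(ids)
  x <- mprs_true[, 1L]
  x_std <- as.numeric(scale(x))
  age <- stats::rnorm(n, 73, 7)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  education <- round(stats::rnorm(n, 16, 2.8))
  z <- cbind(age = as.numeric(scale(age)),
             sex = as.numeric(sex == "M"),
             education = as.numeric(scale(education)))
  gamma <- med$gamma %||% c(0, 0, 0)
  m <- med$a * x_std + stats::rnorm(n)
  latent <- med$c * x_std + med$b * m + drop(z %*% gamma)
  y <- stats::rbinom(n, 1L, stats::plogis(latent))

  diagnosis <- character(n)
  idx0 <- which(y == 0L)
  diagnosis[idx0] <- sample(c("CN", "SMC"), length(idx0), replace = TRUE,
                            prob = c(0.8, 0.2))
  idx1 <- which(y == 1L)
  if (length(idx1) > 0L) {
    terc <- cut(rank(latent[idx1], ties.method = "first"),
                breaks = 3L, labels = c("EMCI", "LMCI", "AD"))
    diagnosis[idx1] <- as.character(terc)
  }

  amyg_left <- 0.62 - 0.03 * m
  amyg_right <- 0.58 - 0.03 * m + stats::rnorm(n, 0, 0.005)

  conv_months <- rep(NA_real_, n)
  conv_event <- rep(NA_integer_, n)
  mci <- which(diagnosis %in% c("EMCI", "LMCI"))
  if (length(mci) >= 2L) {
    x_mci <- as.numeric(scale(x[mci]))
    sv <- generate_survival_times(x_mci, config$surv,
                                  derive_seed(config$seed, "survival"))
    conv_months[mci] <- sv$conv_months
    conv_event[mci] <- sv$conv_event
  }
  data.frame(individual_id = ids, diagnosis = diagnosis, age = age,
             sex = sex, education = education, amyg_left = amyg_left,
             amyg_right = amyg_right, conv_months = conv_months,
             conv_event = conv_event, stringsAsFactors = FALSE)
}

#' Monte-Carlo oracle for the generative mediation effects
#'
#' Computes the true average causal mediation effect (ACME), average direct
#' effect (ADE), total effect and mediated proportion implied by the
#' generative model (x standardized; treatment contrast x = -1 vs x = +1,
#' i.e. mean +/- 1 SD), by plain Monte-Carlo over the mediator noise. This
#' is independent of the estimation code in [mediation_analysis()] and is
#' stored with each simulated dataset for recovery tests.
#'
#' @param a,b,c_direct Generative path coefficients.
#' @param n_draws Monte-Carlo draws (default 1e6).
#' @param seed Integer seed.
#' @return List with `acme`, `ade`, `total`, `prop_mediated`.
#' @export
true_mediation_effects <- function(a, b, c_direct, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  eps <- stats::rnorm(n_draws)
  t0 <- -1; t1 <- 1
  y_tm <- function(t, t_m) stats::plogis(c_direct * t + b * (a * t_m + eps))
  acme <- (mean(y_tm(t0, t1) - y_tm(t0, t0)) +
             mean(y_tm(t1, t1) - y_tm(t1, t0))) / 2
  ade <- (mean(y_tm(t1, t0) - y_tm(t0, t0)) +
            mean(y_tm(t1, t1) - y_tm(t0, t1))) / 2
  total <- acme + ade
  list(acme = acme, ade = ade, total = total,
       prop_mediated = acme / total)
}

#' Generate tissue expression with planted co-expression
#'
#' In the target tissue, genes of planted module k load sqrt(rho) on a
#' shared per-sample latent factor (residual variance 1 - rho), so the
#' expected within-module pairwise Pearson correlation is rho. All other
#' genes, and all genes in non-target tissues, are independent N(0, 1).
#'
#' @param network Output of [generate_network()].
#' @param config A [simulation_config()].
#' @return Named list of genes x samples matrices, one per tissue, each
#'   with a `tissue_label` attribute.
#' @export
generate_expression <- function(network, config) {
  set.seed(derive_seed(config$seed, "expression"))
  ex <- config$expression
  n_s <- ex$n_samples
  out <- list()
  for (tissue in ex$tissues) {
    mat <- matrix(stats::rnorm(length(network$genes) * n_s),
                  nrow = length(network$genes),
                  dimnames = list(network$genes,
                                  sprintf("%s_S%03d", tissue, seq_len(n_s))))
    if (tissue == ex$target_tissue && ex$rho > 0) {
      for (k in seq_along(network$membership)) {
        members <- network$membership[[k]]
        f <- stats::rnorm(n_s)
        mat[members, ] <- sqrt(ex$rho) * matrix(f, length(members), n_s,
                                                byrow = TRUE) +
          sqrt(1 - ex$rho) * mat[members, ]
      }
    }
    attr(mat, "tissue_label") <- tissue
    out[[tissue]] <- mat
  }
  out
}

#' Simulate a complete synthetic study
#'
#' Runs every generator under one seed and (optionally) writes all pipeline
#' input files plus a `ground_truth.json` recording planted structure and
#' true parameter values.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory; created if needed.
#' @param n_truth_draws Monte-Carlo draws for the mediation oracle.
#' @return List with all generated components and `ground_truth`.
#' @export
simulate_dataset <- function(config, out_dir = NULL, n_truth_draws = 1e6) {
  network <- generate_network(config)
  scores <- generate_gene_scores(network, config)
  geno <- generate_genotypes_and_sumstats(config, network)
  pheno <- generate_phenotypes(geno$mprs_true, config)
  expr <- generate_expression(network, config)
  med <- config$mediation
  truth_med <- true_mediation_effects(med$a, med$b, med$c,
                                      n_draws = n_truth_draws,
                                      seed = derive_seed(config$seed, "truth"))
  ground_truth <- list(
    planted_modules = network$membership,
    module_snps = geno$module_snps,
    target_cohens_d = config$target_cohens_d,
    group = as.list(geno$group),
    mediation = c(med[c("a", "b", "c")], truth_med),
    log_hr_per_sd = config$surv$log_hr_per_sd,
    expression_rho = config$expression$rho,
    seed = config$seed
  )
  res <- list(network = network, scores = scores, genotypes = geno$genotypes,
              sumstats = geno$sumstats, annotation = geno$annotation,
              group = geno$group, mprs_true = geno$mprs_true,
              phenotypes = pheno, expression = expr,
              ground_truth = ground_truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    utils::write.table(network$edges, fp("ppi_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(scores, fp("gene_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(geno$annotation, fp("gene_annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gm <- geno$genotypes
    dos_out <- data.frame(individual_id = gm$individual_ids,
                          gm$dosages, check.names = FALSE)
    utils::write.table(dos_out, fp("genotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(snp_id = gm$snp_ids,
                                  counted_allele = unname(gm$counted_allele),
                                  other_allele = unname(gm$other_allele)),
                       fp("genotypes.tsv.alleles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (lab in names(geno$sumstats)) {
      utils::write.table(geno$sumstats[[lab]],
                         fp(sprintf("sumstats_%s.tsv", lab)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    utils::write.table(pheno, fp("phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (tissue in names(expr)) {
      mat <- expr[[tissue]]
      utils::write.table(data.frame(gene_id = rownames(mat), mat,
                                    check.names = FALSE),
                         fp(sprintf("expression_%s.tsv", tissue)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    gmt_lines <- c(
      vapply(seq_along(network$membership), function(k) {
        paste(c(sprintf("PLANTED%d", k), "planted module genes",
                network$membership[[k]]), collapse = "\t")
      }, ""),
      paste(c("RANDOM1", "random control set",
              utils::head(setdiff(network$genes,
                                  unlist(network$membership)), 10L)),
            collapse = "\t")
    )
    writeLines(gmt_lines, fp("gene_sets.gmt"))
    jsonlite::write_json(ground_truth, fp("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
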
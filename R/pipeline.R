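#' Pipeline configuration
#'
#' Collects all input paths and analysis parameters for [run_pipeline()].
#' Defaults follow the framework's reference settings: restart probability
#' 0.4 under the hotnet2 convention, +/-20 kb SNP-to-gene windows, 800
#' propagation permutations with minimum module size 3, 1000 random modules
#' for the co-expression null, 5000 mediation bootstrap draws, and
#' Bonferroni control at alpha = 0.05 with the union rule across weight
#' sources.
#'
#' @param edges Path to the PPI edge list TSV.
#' @param gene_scores Path to the gene score table; alternatively supply
#'   `iqt_sumstats` to derive scores by windowed min-p aggregation.
#' @param sumstats Named list of summary-statistics paths (weight sources).
#' @param genotypes Path to the dosage TSV (sidecar at
#'   `<path>.alleles.tsv`) or VCF.
#' @param genotype_format `"dosage_tsv"` or `"vcf"`.
#' @param annotation Path to the gene annotation TSV.
#' @param phenotypes Path to the phenotype TSV.
#' @param expression Named list (tissue -> path) of expression matrices;
#'   optional.
#' @param target_tissue Tissue used for modularity evaluation.
#' @param gmt Optional GMT path for enrichment.
#' @param iqt_sumstats Optional path to trait summary statistics for the
#'   gene-scoring stand-in.
#' @param out_dir Output directory.
#' @param side Label for module ids (e.g. `"left"`).
#' @param beta,convention,window_bp,n_perm_propagation,min_module_size,n_bins
#'   Propagation parameters.
#' @param n_perm_modularity,n_boot_mediation,n_mc_mediation Validation
#'   parameters.
#' @param alpha,adm_rule Module selection parameters.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(edges, gene_scores = NULL, sumstats, genotypes,
                            genotype_format = "dosage_tsv", annotation,
                            phenotypes, expression = NULL,
                            target_tissue = NULL, gmt = NULL,
                            iqt_sumstats = NULL, out_dir, side = "trait",
                            beta = 0.4, convention = "hotnet2",
                            window_bp = 20000, n_perm_propagation = 800,
                            min_module_size = 3, n_bins = 100,
                            n_perm_modularity = 1000,
                            n_boot_mediation = 5000, n_mc_mediation = 100,
                            alpha = 0.05, adm_rule = "union", seed) {
  assert_that(!missing(seed), "a seed is mandatory")
  assert_that(!is.null(gene_scores) || !is.null(iqt_sumstats),
              "supply gene_scores or iqt_sumstats")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

check_inputs_exist <- function(cfg) {
  paths <- c(cfg$edges, cfg$gene_scores, unlist(cfg$sumstats),
             cfg$genotypes, cfg$annotation, cfg$phenotypes,
             unlist(cfg$expression), cfg$gmt, cfg$iqt_sumstats)
  missing <- paths[!file.exists(paths)]
  assert_that(length(missing) == 0L, "missing input file(s): %s",
              paste(missing, collapse = ", "))
}

#' Run the full module-discovery and validation pipeline
#'
#' Stages, in order: gene scoring (optional windowed min-p stand-in),
#' network construction and restriction to the largest component,
#' propagation with permutation-scored SCC modules, module risk scores
#' under every weight source, disease-relevant module selection,
#' co-expression modularity / tissue specificity / enrichment (when
#' expression and gene sets are supplied), and clinical validation
#' (staging, conversion survival, mediation) for each selected module.
#' Every stage writes its table under `out_dir`; `manifest.json` records
#' package version, parameters, seed and record counts. Reruns with the
#' same config and seed reproduce all outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisible list with all stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  check_inputs_exist(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(cfg$out_dir, x)

  annotation <- read_gene_annotation(cfg$annotation)
  sumstats <- lapply(cfg$sumstats, read_sumstats)
  phenotypes <- read_phenotypes(cfg$phenotypes)
  genotypes <- read_genotypes(cfg$genotypes, cfg$genotype_format)

  if (!is.null(cfg$gene_scores)) {
    scores <- read_gene_scores(cfg$gene_scores)
  } else {
    iqt <- read_sumstats(cfg$iqt_sumstats)
    iqt_map <- map_snps_to_genes(iqt, annotation, cfg$window_bp)
    scores <- aggregate_gene_p(iqt, iqt_map)
  }

  edges <- read_edge_list(cfg$edges)
  network <- largest_connected_component(
    build_weighted_network(edges, scores))

  detection <- select_cut_and_score(
    network, beta = cfg$beta, convention = cfg$convention,
    n_perm = cfg$n_perm_propagation, min_size = cfg$min_module_size,
    seed = derive_seed(cfg$seed, "propagation"), n_bins = cfg$n_bins,
    side = cfg$side, alpha = cfg$alpha)
  modules <- detection$modules
  assert_that(nrow(modules) > 0L,
              "no candidate modules passed the permutation screen")

  snp_map <- map_snps_to_genes(sumstats[[1L]], annotation, cfg$window_bp)
  profiles <- mprs_profiles(genotypes, sumstats, modules, snp_map)
  adm <- identify_adms(profiles, phenotypes, alpha = cfg$alpha,
                       rule = cfg$adm_rule)
  write_report(adm, fp("adm.tsv"))

  src_names <- names(cfg$sumstats)
  enrich_mod <- function(col, src) {
    v <- adm[[col]][adm$weight_source == src]
    stats::setNames(v, adm$module_id[adm$weight_source == src])
  }
  modules$p_meta1 <- enrich_mod("p", src_names[1L])[modules$module_id]
  modules$p_meta2 <- if (length(src_names) >= 2L) {
    enrich_mod("p", src_names[2L])[modules$module_id]
  } else NA_real_
  modules$cohens_d <- enrich_mod("cohens_d", src_names[1L])[modules$module_id]
  modules$d_ci_low <- enrich_mod("d_ci_low", src_names[1L])[modules$module_id]
  modules$d_ci_high <- enrich_mod("d_ci_high", src_names[1L])[modules$module_id]
  write_modules(modules, fp("modules.tsv"),
                metadata = list(delta_star = detection$delta_star,
                                beta = cfg$beta, convention = cfg$convention,
                                n_perm = cfg$n_perm_propagation,
                                seed = cfg$seed))

  results <- list(network = network, detection = detection,
                  modules = modules, profiles = profiles, adm = adm)

  if (!is.null(cfg$expression)) {
    expr <- lapply(names(cfg$expression), function(t) {
      read_expression(cfg$expression[[t]], t)
    })
    names(expr) <- names(cfg$expression)
    target <- cfg$target_tissue %||% names(expr)[1L]
    background <- network$genes
    modularity <- do.call(rbind, lapply(seq_len(nrow(modules)), function(i) {
      row <- modularity_permutation(
        expr[[target]], modules$genes[[i]], background,
        n_perm = cfg$n_perm_modularity,
        seed = derive_seed(cfg$seed, paste0("modularity", i)))
      cbind(module_id = modules$module_id[i], row)
    }))
    write_report(modularity, fp("modularity.tsv"))
    results$modularity <- modularity
    others <- setdiff(names(expr), target)
    if (length(others) > 0L && nrow(modules) >= 2L) {
      pcc_target <- vapply(modules$genes, function(g) {
        module_coexpression(expr[[target]], g)
      }, 0)
      spec <- do.call(rbind, lapply(others, function(t) {
        pcc_other <- vapply(modules$genes, function(g) {
          module_coexpression(expr[[t]], g)
        }, 0)
        ts <- tissue_specificity(pcc_target, pcc_other)
        data.frame(target = target, other = t, t = ts$t, p = ts$p,
                   mean_difference = ts$mean_difference)
      }))
      write_report(spec, fp("tissue_specificity.tsv"))
      results$tissue_specificity <- spec
    }
    if (!is.null(cfg$gmt)) {
      gmt <- read_gmt(cfg$gmt)
      enr <- do.call(rbind, lapply(seq_len(nrow(modules)), function(i) {
        cbind(module_id = modules$module_id[i],
              hypergeometric_enrichment(modules$genes[[i]], gmt, background))
      }))
      write_report(enr, fp("enrichment.tsv"))
      results$enrichment <- enr
    }
  }

  selected <- unique(adm$module_id[adm$significant])
  if (length(selected) == 0L) {
    msg_log("run_pipeline", "no disease-relevant module passed Bonferroni; clinical validation skipped")
  }
  staging <- list(); surv_rows <- list(); med_rows <- list()
  y_map <- c(CN = 0, SMC = 0, EMCI = 1, LMCI = 1, AD = 1)
  for (mod in selected) {
    prof <- profiles[profiles$module_id == mod &
                       profiles$weight_source == src_names[1L], ]
    sc <- stats::setNames(prof$score_z, prof$individual_id)
    st <- staging_comparisons(sc, phenotypes)
    staging[[mod]] <- cbind(module_id = mod, st)

    ph <- phenotypes[match(prof$individual_id, phenotypes$individual_id), ]
    mci <- ph$diagnosis %in% c("EMCI", "LMCI") & !is.na(ph$conv_months)
    if (sum(mci) >= 10L && sum(ph$conv_event[mci]) >= 2L) {
      risk <- median_split(prof$score_z[mci])
      if (length(unique(risk)) == 2L) {
        kl <- km_logrank(ph$conv_months[mci], ph$conv_event[mci], risk)
        cov <- data.frame(mprs_z = as.numeric(scale(prof$score_z[mci])),
                          age = ph$age[mci],
                          sex = as.numeric(ph$sex[mci] == "M"),
                          education = ph$education[mci])
        cx <- cox_ph(ph$conv_months[mci], ph$conv_event[mci], cov)
        surv_rows[[mod]] <- data.frame(
          module_id = mod, n = sum(mci), n_events = sum(ph$conv_event[mci]),
          logrank_chi2 = kl$logrank_chi2, logrank_p = kl$logrank_p,
          cox_hr_per_sd = cx$hr[1L], cox_ci_low = cx$ci_low[1L],
          cox_ci_high = cx$ci_high[1L], cox_p = cx$p[1L])
      }
    }
    y <- unname(y_map[ph$diagnosis])
    zcov <- data.frame(age = ph$age, sex = as.numeric(ph$sex == "M"),
                       education = ph$education)
    med <- mediation_analysis(prof$score_z, ph$amyg_left, y, zcov,
                              n_boot = cfg$n_boot_mediation,
                              n_mc = cfg$n_mc_mediation,
                              seed = derive_seed(cfg$seed,
                                                 paste0("mediation", mod)))
    med_rows[[mod]] <- data.frame(
      module_id = mod, acme = med$acme$estimate,
      acme_ci_low = med$acme$ci[1L], acme_ci_high = med$acme$ci[2L],
      acme_p = med$acme$p, ade = med$ade$estimate,
      total_effect = med$total_effect$estimate,
      prop_mediated = med$prop_mediated$estimate,
      prop_ci_low = med$prop_mediated$ci[1L],
      prop_ci_high = med$prop_mediated$ci[2L])
  }
  if (length(staging) > 0L) {
    results$staging <- do.call(rbind, staging)
    write_report(results$staging, fp("staging.tsv"))
  }
  if (length(surv_rows) > 0L) {
    results$survival <- do.call(rbind, surv_rows)
    write_report(results$survival, fp("survival.tsv"))
  }
  if (length(med_rows) > 0L) {
    results$mediation <- do.call(rbind, med_rows)
    write_report(results$mediation, fp("mediation.tsv"))
  }

  manifest <- list(
    package = "mprsnet",
    version = as.character(utils::packageVersion("mprsnet")),
    r_version = R.version.string,
    seed = cfg$seed,
    parameters = cfg[c("beta", "convention", "window_bp",
                       "n_perm_propagation", "min_module_size",
                       "n_perm_modularity", "n_boot_mediation", "alpha",
                       "adm_rule", "side")],
    counts = list(network_genes = length(network$genes),
                  network_edges = nrow(network$edges),
                  candidate_modules = nrow(modules),
                  selected_modules = length(selected)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(results)
}

#' One-command synthetic demonstration
#'
#' Simulates a complete synthetic study under `seed` and runs the full
#' pipeline on it with reference parameters (scaled only where noted via
#' `...`, e.g. smaller `n_perm_propagation` for a quick look).
#'
#' @param out_dir Output directory (`data/` and `results/` are created
#'   inside).
#' @param seed Integer seed.
#' @param config Optional [simulation_config()]; defaults to the package
#'   default with this seed.
#' @param ... Overrides passed to [pipeline_config()].
#' @return Invisible list with `simulation` and `pipeline` results.
#' @export
run_demo <- function(out_dir, seed, config = NULL, ...) {
  data_dir <- file.path(out_dir, "data")
  sim_cfg <- config %||% simulation_config(seed = seed)
  sim <- simulate_dataset(sim_cfg, out_dir = data_dir)
  dp <- function(x) file.path(data_dir, x)
  overrides <- list(...)
  args <- list(
    edges = dp("ppi_edges.tsv"), gene_scores = dp("gene_scores.tsv"),
    sumstats = list(meta1 = dp("sumstats_meta1.tsv"),
                    meta2 = dp("sumstats_meta2.tsv")),
    genotypes = dp("genotypes.tsv"), annotation = dp("gene_annotation.tsv"),
    phenotypes = dp("phenotypes.tsv"),
    expression = stats::setNames(
      as.list(dp(sprintf("expression_%s.tsv", sim_cfg$expression$tissues))),
      sim_cfg$expression$tissues),
    target_tissue = sim_cfg$expression$target_tissue,
    gmt = dp("gene_sets.gmt"), out_dir = file.path(out_dir, "results"),
    seed = seed)
  args[names(overrides)] <- overrides
  cfg <- do.call(pipeline_config, args)
  res <- run_pipeline(cfg)
  invisible(list(simulation = sim, pipeline = res))
}
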
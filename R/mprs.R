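#' Harmonize genotype dosages against meta-GWAS effect alleles
#'
#' Aligns the counted allele of each genotyped SNP with the effect allele
#' of the summary statistics so that dosage x beta is always expressed on
#' the effect-allele scale: matching orientation keeps the dosage, swapped
#' orientation maps g to 2 - g, strand-palindromic SNPs (A/T, C/G) are
#' dropped when `drop_palindromic` (their orientation is unresolvable
#' without strand information), and any other allele pairing is dropped as
#' a mismatch. Nothing here is fatal; every drop is tallied by reason.
#'
#' @param genotypes A `genotype_matrix`.
#' @param sumstats Summary statistics data.frame.
#' @param drop_palindromic Drop A/T and C/G SNPs (default TRUE).
#' @param snp_ids Optional subset of SNP ids to harmonize.
#' @return List with `dosages` (individuals x kept SNPs, effect-allele
#'   scale), `beta` (named vector), and `dropped` (named integer vector of
#'   reasons: `not_in_sumstats`, `palindromic`, `allele_mismatch`).
#' @export
harmonize <- function(genotypes, sumstats, drop_palindromic = TRUE,
                      snp_ids = NULL) {
  ids <- snp_ids %||% genotypes$snp_ids
  ids <- intersect(ids, genotypes$snp_ids)
  dropped <- c(not_in_sumstats = 0L, palindromic = 0L, allele_mismatch = 0L)
  in_ss <- ids %in% sumstats$snp_id
  dropped[["not_in_sumstats"]] <- sum(!in_ss)
  ids <- ids[in_ss]
  ss <- sumstats[match(ids, sumstats$snp_id), ]
  if (drop_palindromic && length(ids) > 0L) {
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    pal <- comp[ss$effect_allele] == ss$other_allele
    dropped[["palindromic"]] <- sum(pal)
    ids <- ids[!pal]
    ss <- ss[!pal, , drop = FALSE]
  }
  counted <- genotypes$counted_allele[ids]
  other <- genotypes$other_allele[ids]
  same <- counted == ss$effect_allele & other == ss$other_allele
  swapped <- counted == ss$other_allele & other == ss$effect_allele
  mism <- !(same | swapped)
  dropped[["allele_mismatch"]] <- sum(mism)
  ids <- ids[!mism]
  same <- same[!mism]
  dos <- genotypes$dosages[, ids, drop = FALSE]
  if (any(!same)) {
    dos[, !same] <- 2 - dos[, !same]
  }
  beta <- stats::setNames(sumstats$beta[match(ids, sumstats$snp_id)], ids)
  list(dosages = dos, beta = beta, dropped = dropped)
}

#' Module-level polygenic risk score
#'
#' Scores each individual on a gene module as the weighted sum of
#' harmonized SNP dosages, MPRS = sum_j sum_k beta_jk * g_jk, over every
#' summary-statistics SNP mapped within the flanking window of a module
#' gene. A SNP falling in the windows of two module genes contributes once
#' by default (`dedup = TRUE`); the literal per-gene double-counting is
#' available for comparison. Missing dosages are mean-imputed per SNP by
#' default.
#'
#' @param genotypes A `genotype_matrix`.
#' @param sumstats Summary statistics data.frame (provides the weights).
#' @param module_genes Character vector of module gene ids.
#' @param snp_gene_map A `snp_gene_map` from [map_snps_to_genes()].
#' @param missing_policy `"mean_impute"` (default), `"drop_individual"`
#'   (scores with any missing dosage become NA), or `"zero"`.
#' @param drop_palindromic Passed to [harmonize()].
#' @param dedup Count a SNP once per module even when mapped to several
#'   module genes (default TRUE).
#' @param weight_source Label recorded with the profile.
#' @param module_id Label for error messages and the output.
#' @return An `mprs_profile` data.frame: `individual_id`, `module_id`,
#'   `weight_source`, `score`, `score_z`; attributes `n_snps_used` and
#'   `dropped`.
#' @export
compute_mprs <- function(genotypes, sumstats, module_genes, snp_gene_map,
                         missing_policy = c("mean_impute", "drop_individual",
                                            "zero"),
                         drop_palindromic = TRUE, dedup = TRUE,
                         weight_source = "meta", module_id = "module") {
  missing_policy <- match.arg(missing_policy)
  present <- intersect(module_genes, names(snp_gene_map$gene_to_snps))
  if (length(present) < length(module_genes)) {
    msg_log("compute_mprs", "module %s: %d gene(s) absent from the SNP map",
            module_id, length(module_genes) - length(present))
  }
  snps <- unlist(snp_gene_map$gene_to_snps[present], use.names = FALSE)
  mult <- table(snps)
  snps <- unique(snps)
  h <- harmonize(genotypes, sumstats, drop_palindromic, snp_ids = snps)
  if (length(h$beta) == 0L) {
    stop(sprintf("module %s has zero usable SNPs after mapping and harmonization",
                 module_id), call. = FALSE)
  }
  beta <- h$beta
  if (!dedup) {
    beta <- beta * as.numeric(mult[names(beta)])
  }
  dos <- h$dosages
  if (missing_policy == "mean_impute") {
    for (j in which(colSums(is.na(dos)) > 0L)) {
      mu <- mean(dos[, j], na.rm = TRUE)
      dos[is.na(dos[, j]), j] <- mu
    }
  } else if (missing_policy == "zero") {
    dos[is.na(dos)] <- 0
  }
  score <- drop(dos %*% beta)  # NA propagates under drop_individual
  s <- stats::sd(score, na.rm = TRUE)
  z <- if (is.finite(s) && s > 0) {
    (score - mean(score, na.rm = TRUE)) / s
  } else {
    rep(0, length(score))
  }
  out <- data.frame(individual_id = rownames(dos), module_id = module_id,
                    weight_source = weight_source, score = as.numeric(score),
                    score_z = z, stringsAsFactors = FALSE)
  attr(out, "n_snps_used") <- length(beta)
  attr(out, "dropped") <- h$dropped
  class(out) <- c("mprs_profile", class(out))
  out
}

#' Score all modules under all weight sources
#'
#' @param genotypes A `genotype_matrix`.
#' @param sumstats_list Named list of summary-statistics data.frames (the
#'   names become `weight_source` labels).
#' @param modules Module data.frame with `module_id` and `genes`
#'   list-column.
#' @param snp_gene_map A `snp_gene_map`.
#' @param ... Passed to [compute_mprs()].
#' @return Long data.frame of per-individual scores across modules and
#'   weight sources.
#' @export
mprs_profiles <- function(genotypes, sumstats_list, modules, snp_gene_map,
                          ...) {
  assert_that(!is.null(names(sumstats_list)),
              "sumstats_list must be a named list")
  out <- list()
  for (src in names(sumstats_list)) {
    for (i in seq_len(nrow(modules))) {
      out[[length(out) + 1L]] <- compute_mprs(
        genotypes, sumstats_list[[src]], modules$genes[[i]], snp_gene_map,
        weight_source = src, module_id = modules$module_id[i], ...)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
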
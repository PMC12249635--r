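#' Mean pairwise co-expression of a gene module
#'
#' The module-level co-expression statistic is the average Pearson
#' correlation over all unordered pairs of module genes, computed on a
#' genes x samples expression matrix. Genes absent from the matrix are
#' dropped with a log line; pairs involving a zero-variance gene are
#' skipped (and counted) rather than failing the module.
#'
#' @param expr Genes x samples numeric matrix (rownames = gene ids).
#' @param genes Module gene ids (>= 2 must be present; >= 3 samples).
#' @return Mean pairwise Pearson r (scalar).
#' @export
module_coexpression <- function(expr, genes) {
  present <- intersect(genes, rownames(expr))
  if (length(present) < length(genes)) {
    msg_log("module_coexpression", "%d module gene(s) absent from expression",
            length(genes) - length(present))
  }
  assert_that(length(present) >= 2, "need >= 2 module genes in the expression matrix")
  assert_that(ncol(expr) >= 3, "need >= 3 expression samples")
  cm <- suppressWarnings(stats::cor(t(expr[present, , drop = FALSE])))
  vals <- cm[upper.tri(cm)]
  n_skip <- sum(is.na(vals))
  if (n_skip > 0L) {
    msg_log("module_coexpression", "%d zero-variance pair(s) skipped", n_skip)
  }
  vals <- vals[!is.na(vals)]
  assert_that(length(vals) >= 1, "no usable gene pairs")
  mean(vals)
}

#' Permutation test of module co-expression
#'
#' Compares the observed module-level mean pairwise correlation with the
#' null distribution obtained from random same-size gene sets drawn from a
#' background gene universe (by default, all genes of the analysis
#' network present in the expression matrix).
#' perm_p = (1 + #\{null >= observed\}) / (1 + n_perm), so p is never 0.
#'
#' @param expr Genes x samples matrix.
#' @param module_genes Module gene ids.
#' @param background_genes Background universe to sample from.
#' @param n_perm Number of random modules (default 1000).
#' @param seed Integer seed.
#' @return One-row data.frame: `tissue_label`, `size`, `observed_pcc`,
#'   `null_mean`, `null_sd`, `perm_p`, `n_perm`.
#' @export
modularity_permutation <- function(expr, module_genes, background_genes,
                                   n_perm = 1000, seed) {
  assert_that(!missing(seed), "a seed is mandatory")
  set.seed(seed)
  background_genes <- intersect(background_genes, rownames(expr))
  size <- length(intersect(module_genes, rownames(expr)))
  assert_that(size >= 2, "module has < 2 genes in the expression matrix")
  assert_that(length(background_genes) >= size,
              "background smaller than the module")
  observed <- module_coexpression(expr, module_genes)
  null_pcc <- vapply(seq_len(n_perm), function(i) {
    module_coexpression(expr, sample(background_genes, size))
  }, 0)
  data.frame(tissue_label = attr(expr, "tissue_label") %||% NA_character_,
             size = size, observed_pcc = observed,
             null_mean = mean(null_pcc), null_sd = stats::sd(null_pcc),
             perm_p = (1 + sum(null_pcc >= observed)) / (1 + n_perm),
             n_perm = n_perm, stringsAsFactors = FALSE)
}

#' Paired test of tissue-specific co-expression
#'
#' Paired two-sided t-test on per-module co-expression differences between
#' a target tissue and a comparison tissue (same modules, same order).
#'
#' @param pcc_target Per-module mean pairwise correlations in the target
#'   tissue.
#' @param pcc_other Matching values in the other tissue.
#' @return List with `t`, `df`, `p`, `mean_difference`.
#' @export
tissue_specificity <- function(pcc_target, pcc_other) {
  assert_that(length(pcc_target) == length(pcc_other) &&
                length(pcc_target) >= 2,
              "need the same >= 2 modules in both tissues")
  d <- pcc_target - pcc_other
  if (stats::sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    return(list(t = t_stat, df = length(d) - 1, p = p,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(pcc_target, pcc_other, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(d))
}

#' Hypergeometric gene-set enrichment over a GMT collection
#'
#' One-sided hypergeometric upper-tail test P(X >= overlap) of the module
#' against each gene set, restricted to a background universe, with
#' Benjamini-Hochberg adjustment across the collection.
#'
#' @param module_genes Module gene ids.
#' @param gmt Named list of gene sets ([read_gmt()]).
#' @param background_genes Background universe.
#' @param fdr_method Adjustment method (default `"BH"`).
#' @return data.frame with `set_id`, `overlap`, `set_size`, `module_size`,
#'   `background_size`, `p`, `fdr`, sorted by p.
#' @export
hypergeometric_enrichment <- function(module_genes, gmt, background_genes,
                                      fdr_method = "BH") {
  bg <- unique(background_genes)
  mod <- intersect(unique(module_genes), bg)
  n_bg <- length(bg)
  assert_that(n_bg >= 1 && length(mod) >= 1,
              "empty background or module after restriction")
  rows <- lapply(names(gmt), function(id) {
    set <- intersect(gmt[[id]], bg)
    ov <- length(intersect(set, mod))
    p <- stats::phyper(ov - 1, length(set), n_bg - length(set),
                       length(mod), lower.tail = FALSE)
    data.frame(set_id = id, overlap = ov, set_size = length(set),
               module_size = length(mod), background_size = n_bg, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = fdr_method)
  out[order(out$p), ]
}
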
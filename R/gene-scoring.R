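#' Map SNPs to genes within a flanking window
#'
#' A SNP maps to a gene when it lies on the same chromosome within
#' `[start - window_bp, end + window_bp]`, both ends inclusive. A SNP may
#' map to several overlapping genes. Chromosomes present among the variants
#' but absent from the annotation produce a warning and leave those SNPs
#' unmapped.
#'
#' @param variants data.frame with `snp_id`, `chrom`, `pos` (summary
#'   statistics qualify).
#' @param annotation Gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`), 1-based inclusive.
#' @param window_bp Flank size in bp (default 20000, i.e. +/-20 kb).
#' @return A `snp_gene_map`: list with `gene_to_snps` and `snp_to_genes`
#'   (named lists) plus the window used.
#' @export
map_snps_to_genes <- function(variants, annotation, window_bp = 20000) {
  assert_that(all(c("snp_id", "chrom", "pos") %in% names(variants)),
              "variants need columns snp_id, chrom, pos")
  missing_chr <- setdiff(unique(variants$chrom), unique(annotation$chrom))
  if (length(missing_chr) > 0L) {
    warning(sprintf("chromosome(s) %s absent from annotation; their SNPs stay unmapped",
                    paste(missing_chr, collapse = ", ")))
  }
  gene_to_snps <- stats::setNames(vector("list", nrow(annotation)),
                                  annotation$gene_id)
  snp_to_genes <- list()
  for (chr in intersect(unique(variants$chrom), unique(annotation$chrom))) {
    v <- variants[variants$chrom == chr, ]
    g <- annotation[annotation$chrom == chr, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = v$pos, width = 1L),
      IRanges::IRanges(start = g$start - window_bp, end = g$end + window_bp)
    )
    snp_hit <- v$snp_id[S4Vectors::queryHits(hits)]
    gene_hit <- g$gene_id[S4Vectors::subjectHits(hits)]
    by_gene <- split(snp_hit, gene_hit)
    gene_to_snps[names(by_gene)] <- Map(c, gene_to_snps[names(by_gene)],
                                        by_gene)
    by_snp <- split(gene_hit, snp_hit)
    snp_to_genes[names(by_snp)] <- Map(c, snp_to_genes[names(by_snp)],
                                       by_snp)
  }
  structure(list(gene_to_snps = gene_to_snps, snp_to_genes = snp_to_genes,
                 window_bp = window_bp),
            class = "snp_gene_map")
}

#' Aggregate SNP p-values to gene level (Bonferroni min-p)
#'
#' A deliberately simple gene score for running the pipeline without an
#' external gene-analysis tool: for a gene with k mapped SNPs,
#' p_gene = min(1, k * min_j p_j). Real gene-analysis output (e.g. MAGMA)
#' can be supplied directly as a gene score table instead. Genes with no
#' mapped SNP are omitted.
#'
#' @param sumstats Summary statistics data.frame (`snp_id`, `p_value`).
#' @param map A `snp_gene_map` from [map_snps_to_genes()].
#' @param method Aggregation method; only `"min_p_bonferroni"`.
#' @return Gene score data.frame (`gene_id`, `p_value`, `n_snps`) with the
#'   method recorded as an attribute.
#' @export
aggregate_gene_p <- function(sumstats, map, method = "min_p_bonferroni") {
  method <- match.arg(method)
  p_of <- stats::setNames(sumstats$p_value, sumstats$snp_id)
  keep <- names(map$gene_to_snps)[lengths(map$gene_to_snps) > 0L]
  rows <- lapply(keep, function(g) {
    snps <- intersect(map$gene_to_snps[[g]], names(p_of))
    if (length(snps) == 0L) return(NULL)
    data.frame(gene_id = g,
               p_value = min(1, length(snps) * min(p_of[snps])),
               n_snps = length(snps), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), p_value = numeric(),
                      n_snps = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}
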
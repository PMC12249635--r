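#' Read an undirected gene-gene edge list
#'
#' Reads a two-column (or wider; extra columns ignored) tab-separated edge
#' list such as a flattened iRefIndex protein-protein interaction export.
#' Self-loops are dropped and duplicate edges are collapsed regardless of
#' orientation, so the result is a set of unique unordered pairs.
#'
#' @param path Path to a TSV file with at least two columns.
#' @param header Logical; does the file carry a header line? (Not
#'   auto-detected.)
#' @return A data.frame with columns `from` and `to` (character), one row
#'   per unique unordered edge, ordered so that `from <= to`.
#' @export
read_edge_list <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines) >= 1L) lines <- lines[-1L]
  lines_idx <- seq_along(lines) + as.integer(header)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lines_idx <- lines_idx[keep]
  if (length(lines) == 0L) {
    warning(sprintf("edge list '%s' is empty", path))
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- lines_idx[which(nf < 2L)[1L]]
    stop(sprintf("malformed edge list line %d in '%s': expected >= 2 tab-separated fields",
                 bad, path), call. = FALSE)
  }
  a <- trimws(vapply(parts, `[[`, "", 1L))
  b <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(a) | !nzchar(b))) {
    bad <- lines_idx[which(!nzchar(a) | !nzchar(b))[1L]]
    stop(sprintf("malformed edge list line %d in '%s': empty gene id", bad, path),
         call. = FALSE)
  }
  n_loop <- sum(a == b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  from <- pmin(a, b)
  to <- pmax(a, b)
  dup <- duplicated(paste(from, to, sep = "\r"))
  msg_log("read_edge_list", "%d lines: kept %d unique edges (%d self-loops, %d duplicates dropped)",
          length(lines), sum(!dup), n_loop, sum(dup))
  data.frame(from = from[!dup], to = to[!dup], stringsAsFactors = FALSE)
}

#' Read disease meta-GWAS summary statistics
#'
#' @param path Delimited text file of per-SNP summary statistics.
#' @param column_map Named character vector mapping the required field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `p_value`) to the column names used in the file.
#' @param sep Field separator (default tab).
#' @return A data.frame with the seven canonical columns. Alleles are
#'   upper-cased. Rows with a missing effect size, identical alleles, or an
#'   allele outside A/C/G/T are dropped and counted in the log; duplicated
#'   SNP identifiers are an error.
#' @export
read_sumstats <- function(path,
                          column_map = c(snp_id = "snp_id", chrom = "chrom",
                                         pos = "pos",
                                         effect_allele = "effect_allele",
                                         other_allele = "other_allele",
                                         beta = "beta", p_value = "p_value"),
                          sep = "\t") {
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "p_value")
  assert_that(all(required %in% names(column_map)),
              "column_map must name all of: %s", paste(required, collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(column_map[required]), names(raw))
  assert_that(length(missing_cols) == 0L,
              "columns absent from '%s': %s", path,
              paste(missing_cols, collapse = ", "))
  ss <- data.frame(
    snp_id = as.character(raw[[column_map[["snp_id"]]]]),
    chrom = as.character(raw[[column_map[["chrom"]]]]),
    pos = as.integer(raw[[column_map[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[column_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[column_map[["other_allele"]]]])),
    beta = as.numeric(raw[[column_map[["beta"]]]]),
    p_value = as.numeric(raw[[column_map[["p_value"]]]]),
    stringsAsFactors = FALSE
  )
  n_in <- nrow(ss)
  n_na_beta <- sum(is.na(ss$beta))
  ss <- ss[!is.na(ss$beta), , drop = FALSE]
  same <- ss$effect_allele == ss$other_allele
  if (any(same)) {
    msg_log("read_sumstats", "%d rows rejected: effect_allele == other_allele", sum(same))
  }
  ss <- ss[!same, , drop = FALSE]
  valid <- ss$effect_allele %in% c("A", "C", "G", "T") &
    ss$other_allele %in% c("A", "C", "G", "T")
  if (any(!valid)) {
    msg_log("read_sumstats", "%d rows rejected: non-ACGT allele", sum(!valid))
  }
  ss <- ss[valid, , drop = FALSE]
  if (anyDuplicated(ss$snp_id)) {
    stop(sprintf("duplicate snp_id in '%s': %s", path,
                 ss$snp_id[duplicated(ss$snp_id)][1L]), call. = FALSE)
  }
  assert_that(all(ss$pos >= 1L), "positions must be 1-based (>= 1)")
  msg_log("read_sumstats", "%d rows read, %d retained (%d missing beta dropped)",
          n_in, nrow(ss), n_na_beta)
  rownames(ss) <- NULL
  ss
}

new_genotype_matrix <- function(dosages, counted_allele, other_allele) {
  stopifnot(is.matrix(dosages))
  assert_that(!is.null(rownames(dosages)) && !is.null(colnames(dosages)),
              "dosage matrix needs individual rownames and SNP colnames")
  assert_that(!anyDuplicated(rownames(dosages)) && !anyDuplicated(colnames(dosages)),
              "individual and SNP ids must be unique")
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  assert_that(all(ok), "dosage values must lie in [0, 2] or be missing")
  assert_that(length(counted_allele) == ncol(dosages) &&
                length(other_allele) == ncol(dosages),
              "one counted/other allele pair required per SNP")
  structure(list(dosages = dosages,
                 individual_ids = rownames(dosages),
                 snp_ids = colnames(dosages),
                 counted_allele = stats::setNames(toupper(counted_allele), colnames(dosages)),
                 other_allele = stats::setNames(toupper(other_allele), colnames(dosages))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read individual-level genotype dosages
#'
#' Two interchange formats are supported: a dosage TSV (individuals in rows,
#' SNPs in columns, first column `individual_id`) with an allele sidecar TSV
#' (`snp_id`, `counted_allele`, `other_allele`), or an uncompressed VCF whose
#' GT field is converted to an ALT-allele count. Multi-allelic VCF records
#' are rejected so that downstream allele harmonization stays unambiguous.
#' Missing genotypes (`NA`, `.`, `./.`) are preserved as `NA`; the missing
#' policy is applied later, at score computation.
#'
#' @param path Path to the dosage TSV or VCF.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @param sidecar Path to the allele sidecar (dosage_tsv only); defaults to
#'   `<path>.alleles.tsv`.
#' @return A `genotype_matrix` object.
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf"),
                           sidecar = paste0(path, ".alleles.tsv")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    assert_that(ncol(raw) >= 2L, "dosage TSV needs individual_id plus >=1 SNP column")
    ids <- as.character(raw[[1L]])
    mat <- as.matrix(raw[, -1L, drop = FALSE])
    suppressWarnings(storage <- apply(mat, 2L, function(col) {
      col[col %in% c("NA", ".", "")] <- NA
      as.numeric(col)
    }))
    storage <- matrix(storage, nrow = nrow(raw),
                      dimnames = list(ids, colnames(raw)[-1L]))
    bad <- !is.na(storage) & (storage < 0 | storage > 2)
    if (any(bad)) {
      stop(sprintf("dosage outside [0,2] at individual '%s', SNP '%s'",
                   rownames(storage)[which(bad, arr.ind = TRUE)[1L, 1L]],
                   colnames(storage)[which(bad, arr.ind = TRUE)[1L, 2L]]),
           call. = FALSE)
    }
    side <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    assert_that(all(c("snp_id", "counted_allele", "other_allele") %in% names(side)),
                "sidecar must have columns snp_id, counted_allele, other_allele")
    if (!setequal(side$snp_id, colnames(storage)) ||
        anyDuplicated(side$snp_id)) {
      stop("sidecar SNP ids do not match dosage matrix columns", call. = FALSE)
    }
    side <- side[match(colnames(storage), side$snp_id), ]
    gm <- new_genotype_matrix(storage, side$counted_allele, side$other_allele)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF genotypes requires the 'vcfR' package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
    if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
      stop("multi-allelic VCF records are not supported; split or filter them first",
           call. = FALSE)
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1L]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }
    dos <- vapply(seq_len(ncol(gt)), function(j) {
      vapply(gt[, j], count_alt, 0)
    }, numeric(nrow(gt)))
    dos <- matrix(as.numeric(dos), nrow = nrow(gt),
                  dimnames = list(fix[, "ID"], colnames(gt)))
    gm <- new_genotype_matrix(t(dos), counted_allele = fix[, "ALT"],
                              other_allele = fix[, "REF"])
  }
  msg_log("read_genotypes", "%d individuals x %d SNPs (%s)",
          nrow(gm$dosages), ncol(gm$dosages), format)
  gm
}

#' Read a gene-level association score table
#'
#' @param path TSV with columns `gene_id` and `p_value` (for example MAGMA
#'   gene analysis output reshaped to two columns).
#' @return A validated data.frame: unique `gene_id`, `p_value` in (0, 1].
#' @export
read_gene_scores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  assert_that(all(c("gene_id", "p_value") %in% names(tab)),
              "gene score table needs columns gene_id, p_value")
  tab <- tab[, c("gene_id", "p_value")]
  tab$gene_id <- as.character(tab$gene_id)
  tab$p_value <- as.numeric(tab$p_value)
  assert_that(!anyDuplicated(tab$gene_id), "gene_id values must be unique")
  assert_that(!anyNA(tab$p_value) && all(is_probability(tab$p_value)),
              "p_value must lie in (0, 1] with no missing values")
  tab
}

#' Read gene annotation intervals (1-based, inclusive)
#'
#' @param path TSV with columns `gene_id`, `chrom`, `start`, `end`.
#' @return A validated data.frame.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  assert_that(all(c("gene_id", "chrom", "start", "end") %in% names(tab)),
              "annotation needs columns gene_id, chrom, start, end")
  tab$gene_id <- as.character(tab$gene_id)
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  assert_that(!anyDuplicated(tab$gene_id), "gene_id values must be unique")
  assert_that(all(tab$start >= 1L) && all(tab$start <= tab$end),
              "need 1 <= start <= end for every gene")
  tab
}

#' Read a genes-by-samples expression matrix
#'
#' @param path TSV, first column `gene_id`, remaining columns samples.
#' @param tissue_label Label attached to the matrix (e.g. `"amygdala"`).
#' @return A numeric matrix (genes x samples) with a `tissue_label`
#'   attribute.
#' @export
read_expression <- function(path, tissue_label) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(raw[[1L]])
  assert_that(!anyDuplicated(genes), "expression gene ids must be unique")
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  attr(mat, "tissue_label") <- tissue_label
  mat
}

DIAGNOSIS_LEVELS <- c("CN", "SMC", "EMCI", "LMCI", "AD")

#' Read the phenotype table
#'
#' Diagnosis uses the five-level staging CN/SMC/EMCI/LMCI/AD. Conversion
#' fields (`conv_months`, `conv_event`) may be missing for individuals
#' outside the conversion cohort, but an observed conversion event requires
#' an observed conversion time.
#'
#' @param path TSV with columns `individual_id`, `diagnosis`, `age`, `sex`,
#'   `education`, `amyg_left`, `amyg_right`, `conv_months`, `conv_event`.
#' @return A validated data.frame.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("individual_id", "diagnosis", "age", "sex", "education",
            "amyg_left", "amyg_right", "conv_months", "conv_event")
  assert_that(all(need %in% names(tab)), "phenotype table needs columns: %s",
              paste(need, collapse = ", "))
  tab$individual_id <- as.character(tab$individual_id)
  assert_that(!anyDuplicated(tab$individual_id), "individual ids must be unique")
  assert_that(all(tab$diagnosis %in% DIAGNOSIS_LEVELS),
              "diagnosis must be one of %s", paste(DIAGNOSIS_LEVELS, collapse = "/"))
  assert_that(all(tab$sex %in% c("M", "F")), "sex must be M or F")
  assert_that(all(is.na(tab$conv_event) | tab$conv_event %in% c(0, 1)),
              "conv_event must be 0/1 or missing")
  assert_that(all(is.na(tab$conv_months) | tab$conv_months >= 0),
              "conv_months must be non-negative")
  bad <- !is.na(tab$conv_event) & tab$conv_event == 1 & is.na(tab$conv_months)
  assert_that(!any(bad), "conv_event = 1 requires an observed conv_months")
  tab
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return A named list of gene sets; each element carries a `description`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop(sprintf("GMT line %d has %d fields; need set_id, description, >=1 gene",
                 which(nf < 3L)[1L], nf[nf < 3L][1L]), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  assert_that(!anyDuplicated(ids), "duplicate gene-set ids in GMT")
  sets <- lapply(parts, function(p) {
    genes <- unique(p[-(1:2)])
    attr(genes, "description") <- p[[2L]]
    genes
  })
  stats::setNames(sets, ids)
}
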
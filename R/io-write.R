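MODULE_TSV_COLUMNS <- c("module_id", "side", "size", "genes", "perm_p",
                        "p_meta1", "p_meta2", "cohens_d", "d_ci_low",
                        "d_ci_high")

#' Write a module table to TSV (+ JSON sidecar)
#'
#' The TSV carries one row per module with the member genes comma-joined;
#' a JSON sidecar (`<path>.json`) holds the same content plus free-form
#' metadata (parameters, seeds). `write_modules()` followed by
#' [read_modules()] is an identity on all module fields.
#'
#' @param modules A data.frame with columns `module_id`, `side`, `genes`
#'   (list-column of character vectors), `perm_p`, and optionally
#'   `p_meta1`, `p_meta2`, `cohens_d`, `d_ci_low`, `d_ci_high`.
#' @param path Output TSV path.
#' @param metadata Optional named list stored in the JSON sidecar.
#' @export
write_modules <- function(modules, path, metadata = list()) {
  out <- data.frame(module_id = character(), side = character(),
                    size = integer(), genes = character(),
                    perm_p = numeric(), p_meta1 = numeric(),
                    p_meta2 = numeric(), cohens_d = numeric(),
                    d_ci_low = numeric(), d_ci_high = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(modules) > 0L) {
    get_num <- function(col) {
      if (col %in% names(modules)) as.numeric(modules[[col]]) else rep(NA_real_, nrow(modules))
    }
    out <- data.frame(
      module_id = as.character(modules$module_id),
      side = as.character(modules$side),
      size = lengths(modules$genes),
      genes = vapply(modules$genes, paste, "", collapse = ","),
      perm_p = get_num("perm_p"),
      p_meta1 = get_num("p_meta1"),
      p_meta2 = get_num("p_meta2"),
      cohens_d = get_num("cohens_d"),
      d_ci_low = get_num("d_ci_low"),
      d_ci_high = get_num("d_ci_high"),
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(modules = out, metadata = metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a module table written by [write_modules()]
#'
#' @param path TSV path.
#' @return A data.frame with `genes` as a list-column.
#' @export
read_modules <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(module_id = "character",
                                          side = "character"))
  assert_that(all(MODULE_TSV_COLUMNS %in% names(tab)),
              "module table needs columns: %s",
              paste(MODULE_TSV_COLUMNS, collapse = ", "))
  tab$genes <- lapply(strsplit(tab$genes, ",", fixed = TRUE), as.character)
  assert_that(all(tab$size == lengths(tab$genes)),
              "module size column disagrees with the gene list")
  tab
}

#' Write a tabular analysis report to TSV
#'
#' @param report A data.frame.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
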
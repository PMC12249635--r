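`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' Per-stage seeds are derived deterministically from one global seed and a
#' stage name, so independent pipeline stages draw from decoupled random
#' streams while the whole run remains reproducible from a single integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"propagation"`).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit R integer
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Stage-scoped logging used by all readers and pipeline stages; every
# dropped or filtered record is counted through here.
msg_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

is_probability <- function(p) is.finite(p) & p > 0 & p <= 1

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests in the family.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 18093)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  assert_that(is.numeric(m) && length(m) == 1L && m >= 1,
              "m must be a positive test count, got %s", format(m))
  alpha / m
}
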
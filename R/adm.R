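#' Two-sample t-test (Welch or Student)
#'
#' A direct implementation kept deliberately transparent (and cross-checked
#' against [stats::t.test()] in the test suite), with explicit behaviour in
#' the degenerate zero-variance cases: equal means give t = 0, p = 1;
#' unequal means with zero variance give an infinite statistic and p = 0.
#'
#' @param x,y Numeric samples (each n >= 2, finite).
#' @param variant `"welch"` (default) or `"student"` (pooled variance).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  assert_that(length(x) >= 2 && length(y) >= 2 && all(is.finite(c(x, y))),
              "each group needs >= 2 finite observations")
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  md <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    if (md == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(md) * Inf, df = n1 + n2 - 2, p = 0))
  }
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  t_stat <- md / sqrt(se2)
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Cohen's d with a normal-approximation confidence interval
#'
#' d = (mean(x) - mean(y)) / s_pooled with
#' SE = sqrt((n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2))) and a symmetric
#' z-interval.
#'
#' @param x,y Numeric samples.
#' @param level Confidence level (default 0.95).
#' @return List with `d`, `ci_low`, `ci_high`.
#' @export
cohens_d_ci <- function(x, y, level = 0.95) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  d <- (mean(x) - mean(y)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(d = d, ci_low = d - zq * se, ci_high = d + zq * se)
}

#' Identify disease-relevant modules by case-control score differences
#'
#' For every candidate module and every weight source, the module scores of
#' the case group are compared with the control group by a two-sample
#' t-test. The significance threshold is Bonferroni-corrected over the
#' total number of candidate modules (all sides pooled; the denominator is
#' the module count, not modules x sources). Under the default `"union"`
#' rule a module is disease-relevant when it passes the corrected threshold
#' under at least one weight source; `"intersection"` requires all sources.
#'
#' @param profiles Long score data.frame from [mprs_profiles()]
#'   (`individual_id`, `module_id`, `weight_source`, `score`).
#' @param phenotypes Phenotype data.frame with `individual_id`,
#'   `diagnosis`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param rule `"union"` (default) or `"intersection"`.
#' @param case_group,control_group Diagnosis labels compared (defaults AD
#'   vs CN).
#' @param m Total number of candidate modules for the Bonferroni
#'   denominator; defaults to the number of distinct modules in `profiles`.
#' @param variant t-test variant (default `"welch"`).
#' @return A data.frame with one row per module x weight source (`t`, `p`,
#'   `cohens_d`, `d_ci_low`, `d_ci_high`, `significant_source`) plus a
#'   per-module `significant` flag; attribute `alpha_corrected` carries the
#'   threshold used.
#' @export
identify_adms <- function(profiles, phenotypes, alpha = 0.05,
                          rule = c("union", "intersection"),
                          case_group = "AD", control_group = "CN",
                          m = NULL, variant = "welch") {
  rule <- match.arg(rule)
  m <- m %||% length(unique(profiles$module_id))
  assert_that(m >= 1, "the candidate module count m must be positive")
  thr <- bonferroni_threshold(alpha, m)
  dx <- stats::setNames(phenotypes$diagnosis, phenotypes$individual_id)
  rows <- list()
  for (mod in unique(profiles$module_id)) {
    for (src in unique(profiles$weight_source)) {
      sub <- profiles[profiles$module_id == mod &
                        profiles$weight_source == src, ]
      g <- dx[sub$individual_id]
      x <- sub$score[!is.na(g) & g == case_group]
      y <- sub$score[!is.na(g) & g == control_group]
      assert_that(length(x) >= 2 && length(y) >= 2,
                  "groups %s/%s need >= 2 scored individuals each",
                  case_group, control_group)
      tt <- two_sample_t(x, y, variant)
      dd <- cohens_d_ci(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = mod, weight_source = src, t = tt$t, p = tt$p,
        cohens_d = dd$d, d_ci_low = dd$ci_low, d_ci_high = dd$ci_high,
        significant_source = tt$p < thr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  agg <- tapply(out$significant_source, out$module_id,
                if (rule == "union") any else all)
  out$significant <- as.logical(agg[out$module_id])
  attr(out, "alpha_corrected") <- thr
  attr(out, "m") <- m
  attr(out, "rule") <- rule
  out
}
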
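#' Pairwise diagnostic staging comparisons
#'
#' Welch two-sided t-tests of a per-individual score (module risk score or
#' imaging trait) between every unordered pair of diagnostic groups with at
#' least two members each. Raw p-values are reported without multiplicity
#' adjustment, as the comparisons are descriptive.
#'
#' @param values Named numeric vector (names = individual ids).
#' @param phenotypes Phenotype data.frame (`individual_id`, `diagnosis`).
#' @param groups Diagnostic groups in staging order.
#' @return data.frame with `group1`, `group2`, `n1`, `n2`, `t`, `p`.
#' @export
staging_comparisons <- function(values, phenotypes,
                                groups = DIAGNOSIS_LEVELS) {
  dx <- stats::setNames(phenotypes$diagnosis, phenotypes$individual_id)
  by_group <- lapply(groups, function(g) {
    v <- values[names(values) %in% names(dx)[dx == g]]
    v[is.finite(v)]
  })
  names(by_group) <- groups
  usable <- groups[vapply(by_group, length, 0L) >= 2L]
  rows <- list()
  for (i in seq_along(usable)) {
    for (j in seq_along(usable)) {
      if (j <= i) next
      tt <- two_sample_t(by_group[[usable[i]]], by_group[[usable[j]]],
                         variant = "welch")
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = usable[i], group2 = usable[j],
        n1 = length(by_group[[usable[i]]]),
        n2 = length(by_group[[usable[j]]]),
        t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out %||% data.frame(group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(), t = numeric(),
                      p = numeric())
}

#' Median split into high- and low-risk groups
#'
#' Individuals strictly above the median are high-risk; values exactly at
#' the median go to the low-risk group, making the split deterministic.
#'
#' @param scores Numeric vector.
#' @return Character vector `"high"` / `"low"`.
#' @export
median_split <- function(scores) {
  ifelse(scores > stats::median(scores), "high", "low")
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group plus the two-group log-rank
#' chi-square (1 df). Right-censored individuals contribute to risk sets
#' until their censoring time. A group without any event is tolerated and
#' logged.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 = converted, 0 = censored).
#' @param group_labels Grouping with exactly two levels.
#' @return List with `km_curves` (named list of data.frames `time`,
#'   `surv`), `logrank_chi2`, `logrank_p`.
#' @export
km_logrank <- function(times, events, group_labels) {
  assert_that(all(times >= 0) && all(events %in% c(0, 1)),
              "need times >= 0 and events in {0, 1}")
  group_labels <- as.character(group_labels)
  lev <- sort(unique(group_labels))
  assert_that(length(lev) == 2L, "log-rank here compares exactly 2 groups")
  for (g in lev) {
    if (sum(events[group_labels == g]) == 0L) {
      msg_log("km_logrank", "group '%s' has no events", g)
    }
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ group_labels)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- lapply(lev, function(g) {
    idx <- strata == paste0("group_labels=", g)
    data.frame(time = fit$time[idx], surv = fit$surv[idx])
  })
  names(curves) <- lev
  sd <- survival::survdiff(survival::Surv(times, events) ~ group_labels)
  list(km_curves = curves, logrank_chi2 = unname(sd$chisq),
       logrank_p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards model for conversion risk
#'
#' Partial-likelihood fit (Efron tie handling by default, appropriate for
#' monthly visit times) of conversion on a standardized module risk score
#' and confounders, with Wald confidence intervals. The first column of
#' `covariates` is conventionally the standardized score, so its hazard
#' ratio reads per SD.
#'
#' @param times Follow-up times.
#' @param events Event indicators.
#' @param covariates data.frame of numeric covariates (e.g. `mprs_z`,
#'   `age`, `sex`, `education`).
#' @param ties Tie handling (default `"efron"`).
#' @param level Confidence level (default 0.95).
#' @return data.frame with one row per covariate: `coef`, `hr`, `ci_low`,
#'   `ci_high`, `se`, `p`.
#' @export
cox_ph <- function(times, events, covariates, ties = "efron",
                   level = 0.95) {
  stopifnot(is.data.frame(covariates))
  constant <- vapply(covariates, function(v) stats::sd(as.numeric(v)) == 0,
                     TRUE)
  assert_that(!any(constant), "constant covariate(s): %s",
              paste(names(covariates)[constant], collapse = ", "))
  assert_that(sum(events) >= 1, "need at least one event")
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (!is.null(fit$info) && isFALSE(fit$info$converged)) {
    stop("Cox partial-likelihood maximization did not converge", call. = FALSE)
  }
  coefs <- stats::coef(fit)
  if (any(abs(coefs) > 20)) {
    stop("Cox fit shows separation (|coef| > 20); check the design",
         call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(covariate = names(coefs), coef = unname(coefs),
             hr = exp(unname(coefs)),
             ci_low = exp(unname(coefs) - zq * se),
             ci_high = exp(unname(coefs) + zq * se), se = se,
             p = 2 * stats::pnorm(-abs(unname(coefs) / se)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Counterfactual mediation effects for fitted mediator (linear) and
# outcome (logistic) models, on the probability scale, using common
# mediator noise across treatment levels so the averaged decomposition
# acme + ade = total holds exactly.
mediation_point <- function(fit_m, fit_y, x, z, n_mc, eps = NULL) {
  n <- length(x)
  t0 <- mean(x) - stats::sd(x)
  t1 <- mean(x) + stats::sd(x)
  am <- stats::coef(fit_m)
  sigma <- summary(fit_m)$sigma
  gy <- stats::coef(fit_y)
  zmat <- if (is.null(z)) matrix(0, n, 0) else as.matrix(z)
  z_m <- if (ncol(zmat) > 0) drop(zmat %*% am[-(1:2)]) else 0
  z_y <- if (ncol(zmat) > 0) drop(zmat %*% gy[-(1:3)]) else 0
  if (is.null(eps)) eps <- matrix(stats::rnorm(n * n_mc), n, n_mc)
  m_at <- function(t) am[[1]] + am[[2]] * t + z_m + sigma * eps
  y_at <- function(t, m) stats::plogis(gy[[1]] + gy[[2]] * t + gy[[3]] * m +
                                         z_y)
  m0 <- m_at(t0); m1 <- m_at(t1)
  acme <- (mean(y_at(t0, m1) - y_at(t0, m0)) +
             mean(y_at(t1, m1) - y_at(t1, m0))) / 2
  ade <- (mean(y_at(t1, m0) - y_at(t0, m0)) +
            mean(y_at(t1, m1) - y_at(t0, m1))) / 2
  c(acme = acme, ade = ade, total = acme + ade)
}

#' Causal mediation analysis with nonparametric bootstrap
#'
#' Estimates how much of the effect of a continuous exposure (module risk
#' score) on a binary outcome (diagnostic status) flows through a
#' continuous mediator (the imaging trait). A linear model
#' m ~ x + z and a logistic model y ~ x + m + z are fitted; the average
#' causal mediation effect (ACME), average direct effect (ADE) and total
#' effect are computed on the probability scale by counterfactual
#' simulation between the treatment levels mean(x) +/- sd(x), averaging
#' over the empirical covariate distribution and `n_mc` Monte-Carlo draws
#' of the mediator. Common mediator noise across treatment levels makes
#' acme + ade = total exact. A nonparametric bootstrap (resampling
#' individuals, refitting both models) yields percentile confidence
#' intervals and sign-crossing p-values (doubled tail proportion, floored
#' at 1/n_boot). Bootstrap draws whose logistic fit fails to converge are
#' redrawn (at most 10% of draws may be discarded).
#'
#' @param x Continuous exposure.
#' @param m Continuous mediator.
#' @param y Binary outcome (0/1).
#' @param z Optional covariate data.frame (age, sex, education).
#' @param n_boot Bootstrap replicates (default 5000).
#' @param n_mc Monte-Carlo mediator draws per evaluation (default 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A `mediation_result` list: `acme`, `ade`, `total_effect`,
#'   `prop_mediated`, each with `ci` and `p`; plus `n_boot`,
#'   `n_discarded`.
#' @export
mediation_analysis <- function(x, m, y, z = NULL, n_boot = 5000,
                               n_mc = 100, seed, level = 0.95) {
  assert_that(!missing(seed), "a seed is mandatory")
  assert_that(all(y %in% c(0, 1)), "y must be binary 0/1")
  n <- length(x)
  assert_that(length(m) == n && length(y) == n, "x, m, y lengths differ")
  if (!is.null(z)) {
    z <- as.data.frame(z)
    z[] <- lapply(z, as.numeric)
    assert_that(nrow(z) == n, "z must have one row per individual")
  }
  set.seed(seed)
  fit_models <- function(xi, mi, yi, zi) {
    if (is.null(zi) || ncol(zi) == 0) {
      fm <- stats::lm(mi ~ xi)
      fy <- suppressWarnings(stats::glm(yi ~ xi + mi, family = stats::binomial()))
    } else {
      zm <- as.matrix(zi)
      fm <- stats::lm(mi ~ xi + zm)
      fy <- suppressWarnings(stats::glm(yi ~ xi + mi + zm,
                                        family = stats::binomial()))
    }
    list(fm = fm, fy = fy)
  }
  fits <- fit_models(x, m, y, z)
  eps <- matrix(stats::rnorm(n * n_mc), n, n_mc)
  point <- mediation_point(fits$fm, fits$fy, x, z, n_mc, eps)
  point <- c(point, prop_mediated = unname(point["acme"] / point["total"]))

  boot <- matrix(NA_real_, n_boot, 4L,
                 dimnames = list(NULL, c("acme", "ade", "total",
                                         "prop_mediated")))
  n_discarded <- 0L
  max_discard <- ceiling(0.1 * n_boot)
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    zb <- if (is.null(z)) NULL else z[idx, , drop = FALSE]
    fb <- fit_models(x[idx], m[idx], y[idx], zb)
    if (!fb$fy$converged) {
      n_discarded <- n_discarded + 1L
      if (n_discarded > max_discard) {
        stop("more than 10% of bootstrap logistic fits failed to converge",
             call. = FALSE)
      }
      next
    }
    pb <- mediation_point(fb$fm, fb$fy, x[idx], zb, n_mc,
                          matrix(stats::rnorm(n * n_mc), n, n_mc))
    boot[b, ] <- c(pb, unname(pb["acme"] / pb["total"]))
    b <- b + 1L
  }
  if (n_discarded > 0L) {
    msg_log("mediation", "%d non-converged bootstrap draw(s) redrawn",
            n_discarded)
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  summarize <- function(name) {
    bs <- boot[, name]
    p <- 2 * min(mean(bs <= 0), mean(bs >= 0))
    list(estimate = unname(point[[name]]),
         ci = unname(stats::quantile(bs, qs, na.rm = TRUE)),
         p = max(p, 1 / n_boot))
  }
  structure(list(acme = summarize("acme"), ade = summarize("ade"),
                 total_effect = summarize("total"),
                 prop_mediated = summarize("prop_mediated"),
                 n_boot = n_boot, n_mc = n_mc, n_discarded = n_discarded),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(s, nm) {
    sprintf("%-14s %8.4f  [%8.4f, %8.4f]  p = %.4g", nm, s$estimate,
            s$ci[1], s$ci[2], s$p)
  }
  cat("Causal mediation analysis (", x$n_boot, " bootstrap draws)\n",
      fmt(x$acme, "ACME"), "\n", fmt(x$ade, "ADE"), "\n",
      fmt(x$total_effect, "Total effect"), "\n",
      fmt(x$prop_mediated, "Prop. mediated"), "\n", sep = "")
  invisible(x)
}
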
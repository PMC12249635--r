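test_that("staging comparisons produce one row per usable group pair", {
  set.seed(20)
  ids <- sprintf("I%03d", 1:250)
  dx <- rep(c("CN", "SMC", "EMCI", "LMCI", "AD"), each = 50)
  pheno <- data.frame(individual_id = ids, diagnosis = dx,
                      stringsAsFactors = FALSE)
  vals <- stats::setNames(rnorm(250), ids)
  st <- staging_comparisons(vals, pheno)
  expect_equal(nrow(st), choose(5, 2))
  expect_setequal(unique(c(st$group1, st$group2)),
                  c("CN", "SMC", "EMCI", "LMCI", "AD"))

  # identical samples in two groups -> p = 1
  vals2 <- vals
  vals2[dx == "SMC"] <- vals2[dx == "CN"]
  st2 <- staging_comparisons(vals2, pheno)
  expect_equal(st2$p[st2$group1 == "CN" & st2$group2 == "SMC"], 1)
})

test_that("monotone group shifts separate adjacent stages with power", {
  set.seed(21)
  wins <- 0L
  for (rep in 1:10) {
    ids <- sprintf("I%04d", 1:1000)
    dx <- rep(c("CN", "SMC", "EMCI", "LMCI", "AD"), each = 200)
    shift <- rep(seq(0, 2, by = 0.5), each = 200)
    vals <- stats::setNames(rnorm(1000) + shift, ids)
    pheno <- data.frame(individual_id = ids, diagnosis = dx,
                        stringsAsFactors = FALSE)
    st <- staging_comparisons(vals, pheno)
    adjacent <- st[paste(st$group1, st$group2) %in%
                     c("CN SMC", "SMC EMCI", "EMCI LMCI", "LMCI AD"), ]
    if (all(adjacent$p < 0.05)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("KM without censoring equals the empirical survival function", {
  km <- km_logrank(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                   rep(c("a", "b"), each = 3))
  for (g in c("a", "b")) {
    expect_equal(km$km_curves[[g]]$time, c(1, 2, 3))
    expect_equal(km$km_curves[[g]]$surv, c(2 / 3, 1 / 3, 0))
  }
  expect_equal(km$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(km$logrank_p, 1, tolerance = 1e-12)
})

# Direct risk-table log-rank oracle (O - E and hypergeometric variance).
logrank_oracle <- function(times, events, group) {
  lev <- sort(unique(group))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == lev[1])
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("log-rank matches the risk-table oracle and is label-symmetric", {
  times <- c(1, 2, 3, 4)
  events <- rep(1, 4)
  grp <- c("A", "A", "B", "B")
  km <- suppressMessages(km_logrank(times, events, grp))
  expect_equal(km$logrank_chi2, logrank_oracle(times, events, grp),
               tolerance = 1e-10)

  set.seed(22)
  for (rep in 1:10) {
    n <- 60
    t2 <- rexp(n, 0.1)
    e2 <- rbinom(n, 1, 0.7)
    g2 <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g2)) < 2 || sum(e2) == 0) next
    km2 <- suppressMessages(km_logrank(t2, e2, g2))
    expect_equal(km2$logrank_chi2, logrank_oracle(t2, e2, g2),
                 tolerance = 1e-8)
    swap <- suppressMessages(km_logrank(t2, e2,
                                        ifelse(g2 == "A", "B", "A")))
    expect_equal(swap$logrank_chi2, km2$logrank_chi2, tolerance = 1e-10)
  }
})

test_that("median split sends ties to the low-risk group deterministically", {
  s <- c(1, 2, 2, 3, 5)
  expect_equal(median_split(s), c("low", "low", "low", "high", "high"))
  expect_identical(median_split(s), median_split(s))
})

test_that("Cox on exchangeable duplicated data gives a null hazard ratio", {
  base <- data.frame(time = c(2, 4, 6, 8, 3, 5), event = c(1, 1, 0, 1, 1, 0))
  dat <- rbind(cbind(base, g = 0), cbind(base, g = 1))
  fit <- cox_ph(dat$time, dat$event, data.frame(g = dat$g))
  expect_equal(fit$coef, 0, tolerance = 1e-8)
  expect_equal(fit$hr, 1, tolerance = 1e-8)
})

test_that("Cox errors on constant covariates and separation-scale fits", {
  expect_error(cox_ph(c(1, 2, 3), c(1, 1, 0),
                      data.frame(a = c(1, 1, 1))), "constant")
})

test_that("the mediation decomposition is exact and recovers a null ACME", {
  set.seed(23)
  n <- 500
  x <- rnorm(n)
  m <- rnorm(n)                     # a = 0: no exposure -> mediator path
  y <- rbinom(n, 1, plogis(0.8 * x + 0.5 * m))
  res <- mediation_analysis(x, m, y, n_boot = 99, n_mc = 50, seed = 24)
  expect_equal(res$acme$estimate + res$ade$estimate,
               res$total_effect$estimate, tolerance = 1e-10)
  expect_lt(abs(res$acme$estimate), 0.05)
  expect_true(res$acme$ci[1] <= 0.02 && res$acme$ci[2] >= -0.02)
  expect_gt(res$total_effect$estimate, 0)
  expect_true(res$total_effect$p >= 1 / 99)
})

test_that("full mediation drives the mediated proportion toward one", {
  set.seed(25)
  n <- 2000
  x <- rnorm(n)
  m <- 0.8 * x + rnorm(n)
  y <- rbinom(n, 1, plogis(0.9 * m))  # c = 0: all effect through m
  res <- mediation_analysis(x, m, y, n_boot = 199, n_mc = 50, seed = 26)
  expect_gt(res$prop_mediated$estimate, 0.8)
  expect_true(res$prop_mediated$ci[1] <= 1 && res$prop_mediated$ci[2] >= 0.8)
})

test_that("mediation handles covariates and stays decomposition-exact", {
  set.seed(27)
  n <- 400
  z <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  x <- rnorm(n)
  m <- 0.4 * x + 0.2 * z$age + rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * x + 0.5 * m - 0.3 * z$sex))
  res <- mediation_analysis(x, m, y, z, n_boot = 49, n_mc = 30, seed = 28)
  expect_equal(res$acme$estimate + res$ade$estimate,
               res$total_effect$estimate, tolerance = 1e-10)
  expect_gt(res$acme$estimate, 0)
})
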
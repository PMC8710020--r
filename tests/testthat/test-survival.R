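test_that("KM estimator matches the hand-computed product limit", {
  # times 2, 4+, 6 with events 1, 0, 1
  km <- km_curve(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km_survival(km, c(1, 2, 3, 5, 6, 7)),
               c(1, 2/3, 2/3, 2/3, 0, 0))
  expect_equal(km$median, 6)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(11)
  t <- rexp(200, 0.1)
  km <- km_curve(t, rep(1, 200))
  grid <- quantile(t, c(0.1, 0.3, 0.5, 0.9))
  expect_equal(km_survival(km, grid), vapply(grid, function(g) mean(t > g),
                                             numeric(1)),
               tolerance = 1e-12)
  # properties: starts at 1, non-increasing
  expect_true(all(diff(km$steps$survival) <= 1e-12))
  expect_lte(max(km$steps$survival), 1)
})

test_that("KM with all observations censored stays at 1 with no median", {
  km <- km_curve(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km$steps$survival == 1))
  expect_true(is.na(km$median))
  expect_error(km_curve(c(0, 1), c(1, 1)), class = "nkmihc_stat_error")
})

test_that("log-rank is zero for duplicated groups and matches hand computation", {
  t <- c(2, 3, 5, 7); e <- c(1, 0, 1, 1)
  res0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(res0$chi_square, 0)

  # 6-subject worked example, O-E and variance accumulated by hand
  time <- c(1, 2, 3, 4, 5, 6); event <- c(1, 1, 0, 1, 1, 0)
  grp <- c("a", "b", "a", "b", "a", "b")
  o <- e <- v <- 0
  for (tt in time[event == 1]) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & grp == "a")
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == "a")
    o <- o + d1; e <- e + d * n1 / n
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  want <- (o - e)^2 / v
  res <- logrank_test(time, event, grp)
  expect_equal(res$chi_square, want, tolerance = 1e-12)
  expect_equal(res$observed1, o)
  expect_equal(res$expected1, e, tolerance = 1e-12)
})

test_that("log-rank agrees with survival::survdiff and is label-invariant", {
  skip_if_not_installed("survival")
  set.seed(12)
  t <- rexp(80, 0.1); e <- rbinom(80, 1, 0.7)
  g <- rep(c("a", "b"), 40)
  res <- logrank_test(t, e, g)
  ref <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(res$chi_square, unname(ref$chisq), tolerance = 1e-9)
  flip <- logrank_test(t, e, ifelse(g == "a", "z", "y"))
  expect_equal(flip$chi_square, res$chi_square, tolerance = 1e-12)
  expect_gte(res$chi_square, 0)
  expect_error(logrank_test(t, rep(0, 80), g), class = "nkmihc_stat_error")
})

test_that("log-rank holds its nominal size under the null", {
  set.seed(13)
  ps <- replicate(400, {
    t <- rexp(40, 0.1); e <- rbinom(40, 1, 0.8)
    logrank_test(t, e, rep(c("a", "b"), 20))$p_value
  })
  mcse <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 2 * mcse + 0.01)
})

test_that("cutpoint search equals the brute-force log-rank scan", {
  set.seed(14)
  for (r in 1:50) {
    n <- 60
    x <- round(rnorm(n), 2)
    t <- rexp(n, 0.08 * exp(0.4 * (x > 0)))
    e <- rbinom(n, 1, 0.8)
    if (sum(e) == 0 || length(unique(x)) < 2) next
    cp <- max_sel_cutpoint(t, e, x, minprop = 0.1)
    nmin <- ceiling(0.1 * n)
    cands <- sort(unique(x))
    cands <- cands[vapply(cands, function(c)
      sum(x <= c) >= nmin && sum(x > c) >= nmin, logical(1))]
    zs <- vapply(cands, function(c)
      logrank_test(t, e, ifelse(x <= c, "low", "high"))$z, numeric(1))
    # the scan uses group "high" first alphabetically; compare |z|
    expect_equal(abs(cp$standardized_statistic), max(abs(zs)),
                 tolerance = 1e-9)
    expect_equal(cp$cutpoint, cands[which(abs(zs) > max(abs(zs)) - 1e-12)[1]])
    expect_gte(min(cp$n_low, cp$n_high), nmin)
  }
})

test_that("cutpoint search honours minprop and rejects degenerate covariates", {
  t <- rexp(30, 0.1); e <- rep(1, 30)
  expect_error(max_sel_cutpoint(t, e, rep(1, 30)),
               class = "nkmihc_cutpoint_error")
  x <- c(rep(0, 29), 1)   # no split satisfies minprop = 0.2
  expect_error(max_sel_cutpoint(t, e, x, minprop = 0.2),
               class = "nkmihc_cutpoint_error")
})

test_that("a perfectly separating covariate is cut between the clusters", {
  # covariate < 1 dies early, covariate > 2 survives long
  t <- c(1, 2, 3, 2, 50, 60, 70, 80)
  e <- c(1, 1, 1, 1, 1, 1, 1, 1)
  x <- c(0.1, 0.2, 0.3, 0.4, 2.5, 2.6, 2.7, 2.8)
  cp <- max_sel_cutpoint(t, e, x, minprop = 0.2)
  expect_gte(cp$cutpoint, 0.4)
  expect_lt(cp$cutpoint, 2.5)
})

test_that("a threshold hazard model's cutpoint is recovered near the truth", {
  set.seed(15)
  theta <- 0.3
  cuts <- replicate(20, {
    x <- rnorm(300)
    t <- rexp(300, 0.05 * exp(log(2) * (x > theta)))
    max_sel_cutpoint(t, rep(1, 300), x)$cutpoint
  })
  # central 80% of recovered cutpoints lies in a tight band around theta
  q <- quantile(cuts, c(0.1, 0.9))
  expect_gt(q[[1]], theta - 0.35)
  expect_lt(q[[2]], theta + 0.35)
})

test_that("Cox estimates match survival::coxph with and without ties", {
  skip_if_not_installed("survival")
  set.seed(16)
  n <- 200
  x <- rnorm(n)
  t_free <- rexp(n, 0.1 * exp(0.5 * x))          # tie-free
  e <- rbinom(n, 1, 0.8)
  fit <- cox_univariate(t_free, e, x)
  ref <- survival::coxph(survival::Surv(t_free, e) ~ x)
  expect_lt(abs(fit$log_hazard - unname(coef(ref))), 1e-6)
  expect_lt(abs(fit$standard_error - sqrt(vcov(ref)[1, 1])), 1e-6)

  t_tied <- ceiling(t_free)                       # heavy ties
  for (m in c("efron", "breslow")) {
    fit_t <- cox_univariate(t_tied, e, x, ties = m)
    ref_t <- survival::coxph(survival::Surv(t_tied, e) ~ x, ties = m)
    expect_lt(abs(fit_t$log_hazard - unname(coef(ref_t))), 1e-6)
  }
})

test_that("Efron and Breslow coincide exactly on tie-free data", {
  set.seed(17)
  x <- rnorm(100)
  t <- rexp(100, 0.1 * exp(0.3 * x))
  f1 <- cox_univariate(t, rep(1, 100), x, ties = "efron")
  f2 <- cox_univariate(t, rep(1, 100), x, ties = "breslow")
  expect_lt(abs(f1$log_hazard - f2$log_hazard), 1e-6)
  expect_lt(abs(f1$standard_error - f2$standard_error), 1e-6)
})

test_that("the Cox score test equals the log-rank chi-square on tie-free data", {
  set.seed(18)
  g <- rbinom(120, 1, 0.5)
  t <- rexp(120, 0.1 * exp(0.6 * g))
  e <- rbinom(120, 1, 0.9)
  fit <- cox_univariate(t, e, g)
  lr <- logrank_test(t, e, g)
  expect_lt(abs(fit$score_chisq - lr$chi_square), 1e-6)
})

test_that("Cox rejects constant covariates and reports separation direction", {
  t <- rexp(30, 0.1); e <- rep(1, 30)
  expect_error(cox_univariate(t, e, rep(0, 30)), class = "nkmihc_stat_error")
  expect_error(cox_univariate(t, rep(0, 30), rnorm(30)),
               class = "nkmihc_stat_error")
  # perfect separation: high covariate dies much later
  t2 <- c(1:10, 1001:1010)
  x2 <- rep(c(0, 1), each = 10)
  err <- expect_error(cox_univariate(t2, rep(1, 20), x2),
                      class = "nkmihc_convergence_error")
  expect_match(conditionMessage(err), "-Inf")
})

test_that("a true hazard ratio of 2 is recovered at n = 2000", {
  set.seed(19)
  x <- rbinom(2000, 1, 0.5)
  t <- rexp(2000, 0.05 * exp(log(2) * x))
  fit <- cox_univariate(t, rep(1, 2000), x)
  expect_gt(fit$hazard_ratio, 1.8)
  expect_lt(fit$hazard_ratio, 2.2)
  expect_gt(fit$ci95[["high"]], fit$hazard_ratio)
  expect_lt(fit$ci95[["low"]], fit$hazard_ratio)
})

test_that("Cox estimates are unbiased over replicates for beta in {0, 0.7}", {
  set.seed(20)
  for (beta in c(0, 0.7)) {
    est <- replicate(100, {
      x <- rbinom(2000, 1, 0.5)
      t <- rexp(2000, 0.05 * exp(beta * x))
      cox_univariate(t, rep(1, 2000), x)$log_hazard
    })
    expect_lt(abs(mean(est) - beta), 0.05)
  }
})

test_that("tidy and glance expose the fitted quantities", {
  set.seed(21)
  x <- rbinom(100, 1, 0.5)
  t <- rexp(100, 0.1 * exp(0.5 * x))
  fit <- cox_univariate(t, rep(1, 100), x)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$log_hazard)
  expect_equal(td$hazard.ratio, fit$hazard_ratio)
  gl <- glance(fit)
  expect_equal(gl$n, 100)
  cp <- max_sel_cutpoint(t, rep(1, 100), x, minprop = 0.2)
  expect_equal(glance(cp)$cutpoint, cp$cutpoint)
  expect_s3_class(tidy(cp), "tbl_df")
})

test_that("the survival screen flags a strong protective/adverse effect and records errors", {
  set.seed(22)
  n <- 120
  nk <- rlnorm(n, 3, 0.6)
  t <- rexp(n, 0.01 * exp(1.2 * scale(log(nk))[, 1]))
  df <- tibble::tibble(
    os_months = pmin(t, 120), os_event = as.integer(t <= 120),
    pfs_months = pmin(t, 120), pfs_event = as.integer(t <= 120),
    CD57_NK_cell_tumoral = nk,
    T_cell_tumoral = 5   # constant -> per-combination error, screen continues
  )
  scr <- survival_screen(df, variables = c("CD57_NK_cell", "T_cell"),
                         compartments = "tumoral", endpoints = c("OS", "PFS"))
  nk_row <- scr[scr$variable == "CD57_NK_cell" & scr$endpoint == "OS", ]
  expect_true(nk_row$flag)
  expect_gt(nk_row$hr, 1)
  expect_gte(min(nk_row$n_low, nk_row$n_high), ceiling(0.1 * n))
  t_row <- scr[scr$variable == "T_cell" & scr$endpoint == "OS", ]
  expect_true(is.na(t_row$hr))
  expect_match(t_row$error, "cutpoint")
})

test_that("an empty variable list yields an empty screen table", {
  df <- tibble::tibble(os_months = 1:5, os_event = rep(1, 5),
                       pfs_months = 1:5, pfs_event = rep(1, 5))
  scr <- survival_screen(df, variables = character(0), endpoints = "OS")
  expect_equal(nrow(scr), 0)
  expect_true(all(c("endpoint", "variable", "hr", "p", "flag") %in%
                    names(scr)))
})
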
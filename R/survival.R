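# Survival machinery implemented from first principles: product-limit
# estimator, log-rank test, maximally selected rank-statistic cutpoint and
# univariate Cox proportional hazards (Efron/Breslow ties).

check_surv <- function(time, event) {
  assert_that(length(time) == length(event) && length(time) >= 1,
              "time and event must be non-empty and of equal length",
              "nkmihc_schema_error")
  assert_that(all(is.finite(time)) && all(time > 0),
              "all survival times must be finite and > 0",
              "nkmihc_stat_error")
  assert_that(all(event %in% c(0, 1)), "event must be 0/1",
              "nkmihc_stat_error")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (1 = death/progression).
#' @return An `nk_km` object: step table `time, n_risk, n_event, n_censor,
#'   survival` (right-continuous, `S(0) = 1`), plus the median survival
#'   (first time with `S(t) <= 0.5`, `NA` if never reached).
#' @export
#' @examples
#' km <- km_curve(c(2, 4, 6), c(1, 0, 1))
#' km$median
km_curve <- function(time, event) {
  check_surv(time, event)
  ut <- sort(unique(time))
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  steps <- tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                          n_censor = n_censor, survival = surv)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  structure(list(steps = steps, median = med, n = n,
                 n_events = sum(event)), class = "nk_km")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km An `nk_km` object.
#' @param t Times at which to evaluate the right-continuous step function.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival <- function(km, t) {
  vapply(t, function(ti) {
    if (ti < min(km$steps$time)) return(1)
    idx <- max(which(km$steps$time <= ti))
    km$steps$survival[idx]
  }, numeric(1))
}

#' @export
print.nk_km <- function(x, ...) {
  cat(sprintf("<nk_km: n = %d, events = %d, median = %s>\n", x$n, x$n_events,
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

# Internal: log-rank observed/expected/variance over event times for
# group == levels[1]. Returns list(o, e, v).
logrank_oev <- function(time, event, grp1) {
  ut <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & grp1)
    d_t <- sum(time == t & event == 1)
    d1_t <- sum(time == t & event == 1 & grp1)
    o <- o + d1_t
    e <- e + d_t * n1_t / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  list(o = o, e = e, v = v)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events with hypergeometric variance at each event
#' time; the statistic is chi-square with 1 degree of freedom.
#'
#' @param time,event Survival data (see [km_curve()]).
#' @param group Two-level grouping vector.
#' @return Tibble `chi_square, p_value, z, observed1, expected1, variance,
#'   n, n_events` where `z` is the standardized statistic for the first
#'   (alphabetically) group.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- as.character(group)
  lev <- sort(unique(group))
  assert_that(length(lev) == 2, "need exactly two groups",
              "nkmihc_stat_error")
  if (sum(event) == 0) {
    abort("untestable: all observations censored",
          class = c("nkmihc_stat_error", "nkmihc_error"))
  }
  oev <- logrank_oev(time, event, group == lev[1])
  z <- if (oev$v > 0) (oev$o - oev$e) / sqrt(oev$v) else 0
  chi <- z^2
  tibble::tibble(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 z = z, observed1 = oev$o, expected1 = oev$e,
                 variance = oev$v, n = length(time), n_events = sum(event))
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans every distinct observed covariate value `c` for which both groups
#' `{x <= c}` and `{x > c}` contain at least `ceil(minprop * n)` subjects,
#' computes the standardized log-rank statistic of the split at each, and
#' returns the cutpoint maximizing its absolute value (ties broken by the
#' smallest cutpoint).
#'
#' @param time,event Survival data.
#' @param x Continuous covariate (>= 2 distinct values).
#' @param minprop Minimum fraction of subjects per group (default 0.1).
#' @return An `nk_cutpoint` object: `cutpoint, standardized_statistic,
#'   n_low, n_high, minprop` plus the per-candidate scan table.
#' @export
max_sel_cutpoint <- function(time, event, x, minprop = 0.1) {
  check_surv(time, event)
  assert_that(length(x) == length(time), "covariate length mismatch",
              "nkmihc_schema_error")
  assert_that(minprop > 0 && minprop < 0.5,
              "minprop must lie in (0, 0.5)", "nkmihc_config_error")
  ok <- is.finite(x)
  time <- time[ok]; event <- event[ok]; x <- x[ok]
  n <- length(x)
  if (length(unique(x)) < 2) {
    abort("no cutpoint: covariate is constant",
          class = c("nkmihc_cutpoint_error", "nkmihc_error"))
  }
  if (sum(event) == 0) {
    abort("no cutpoint: all observations censored",
          class = c("nkmihc_cutpoint_error", "nkmihc_error"))
  }
  nmin <- ceiling(minprop * n)
  cand <- sort(unique(x))
  n_low <- vapply(cand, function(c) sum(x <= c), numeric(1))
  keep <- n_low >= nmin & (n - n_low) >= nmin
  cand <- cand[keep]
  if (length(cand) == 0) {
    abort("no cutpoint satisfies the minprop constraint",
          class = c("nkmihc_cutpoint_error", "nkmihc_error"))
  }
  zs <- vapply(cand, function(c) {
    oev <- logrank_oev(time, event, x <= c)
    if (oev$v > 0) (oev$o - oev$e) / sqrt(oev$v) else 0
  }, numeric(1))
  best <- which(abs(zs) == max(abs(zs)))[1]   # ties -> smallest cutpoint
  structure(
    list(cutpoint = cand[best], standardized_statistic = zs[best],
         n_low = sum(x <= cand[best]), n_high = sum(x > cand[best]),
         minprop = minprop, n = n,
         scan = tibble::tibble(cutpoint = cand, z = zs)),
    class = "nk_cutpoint"
  )
}

#' @export
print.nk_cutpoint <- function(x, ...) {
  cat(sprintf("<nk_cutpoint: cut = %g, |z| = %.3f, n_low/n_high = %d/%d>\n",
              x$cutpoint, abs(x$standardized_statistic), x$n_low, x$n_high))
  invisible(x)
}

# Internal: Cox partial log-likelihood, score and information for scalar
# beta with Efron or Breslow tie handling.
cox_lui <- function(beta, time, event, x, ties) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  w <- exp(beta * x)
  # reverse cumulative sums give risk-set sums at the first index of each time
  rc_w <- rev(cumsum(rev(w)))
  rc_xw <- rev(cumsum(rev(x * w)))
  rc_x2w <- rev(cumsum(rev(x^2 * w)))

  uet <- sort(unique(time[event == 1]))      # distinct event times
  i0 <- match(uet, time)                     # first at-risk index per time
  ev <- event == 1
  f <- factor(time[ev], levels = uet)
  d <- as.vector(table(f))
  sum_xd <- as.vector(rowsum(x[ev], f))
  s_d <- as.vector(rowsum(w[ev], f))
  s1_d <- as.vector(rowsum(x[ev] * w[ev], f))
  s2_d <- as.vector(rowsum(x[ev]^2 * w[ev], f))

  # expand one row per event within each tie group (Efron fractions l/d)
  g <- rep(seq_along(uet), d)
  fr <- if (ties == "efron") {
    unlist(lapply(d, function(dd) (seq_len(dd) - 1) / dd), use.names = FALSE)
  } else {
    rep(0, sum(d))
  }
  a <- rc_w[i0][g] - fr * s_d[g]
  a1 <- rc_xw[i0][g] - fr * s1_d[g]
  a2 <- rc_x2w[i0][g] - fr * s2_d[g]

  list(loglik = beta * sum(sum_xd) - sum(log(a)),
       score = sum(sum_xd) - sum(a1 / a),
       info = sum(a2 / a - (a1 / a)^2))
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton-Raphson (tolerance 1e-9, at
#' most 50 iterations) with Efron (default) or Breslow handling of tied
#' event times. The standard error comes from the observed information;
#' the confidence interval and p-value are Wald. The score test at beta = 0
#' is also reported (on a binary covariate with no ties it equals the
#' log-rank chi-square).
#'
#' @param time,event Survival data.
#' @param x Covariate (non-constant; at least one event required).
#' @param ties `"efron"` or `"breslow"`.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return An `nk_cox` object.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbinom(100, 1, 0.5)
#' t <- rexp(100, 0.1 * exp(0.7 * x))
#' fit <- cox_univariate(t, rep(1, 100), x)
#' fit$hazard_ratio
cox_univariate <- function(time, event, x, ties = c("efron", "breslow"),
                           conf_level = 0.95) {
  ties <- match.arg(ties)
  check_surv(time, event)
  assert_that(length(x) == length(time), "covariate length mismatch",
              "nkmihc_schema_error")
  ok <- is.finite(x)
  time <- time[ok]; event <- event[ok]; x <- x[ok]
  if (sum(event) == 0) {
    abort("Cox fit needs at least one event",
          class = c("nkmihc_stat_error", "nkmihc_error"))
  }
  if (stats::sd(x) == 0) {
    abort("singular Cox fit: covariate is constant",
          class = c("nkmihc_stat_error", "nkmihc_error"))
  }
  xc <- x - mean(x)        # centring stabilizes exp() without changing beta
  lui0 <- cox_lui(0, time, event, xc, ties)
  score_chisq <- if (lui0$info > 0) lui0$score^2 / lui0$info else NA_real_

  beta <- 0
  lui <- lui0
  converged <- FALSE
  for (it in seq_len(50)) {
    if (lui$info <= 1e-12) {
      abort("singular Cox fit: information is zero",
            class = c("nkmihc_stat_error", "nkmihc_error"))
    }
    step <- lui$score / lui$info
    step <- max(min(step, 5), -5)    # damp huge early steps
    beta_new <- beta + step
    if (abs(beta_new) > 15) {
      abort(sprintf(
        "monotone partial likelihood (perfect separation); beta diverges towards %s",
        ifelse(beta_new > 0, "+Inf", "-Inf")),
        class = c("nkmihc_convergence_error", "nkmihc_error"))
    }
    lui_new <- cox_lui(beta_new, time, event, xc, ties)
    if (abs(beta_new - beta) < 1e-9 && abs(lui_new$score) < 1e-7) {
      beta <- beta_new; lui <- lui_new; converged <- TRUE
      break
    }
    beta <- beta_new; lui <- lui_new
  }
  if (!converged && abs(lui$score) > 1e-5) {
    abort("Cox Newton-Raphson failed to converge in 50 iterations",
          class = c("nkmihc_convergence_error", "nkmihc_error"))
  }
  se <- 1 / sqrt(lui$info)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  zstat <- beta / se
  structure(
    list(log_hazard = beta, standard_error = se,
         hazard_ratio = exp(beta),
         ci95 = c(low = exp(beta - zq * se), high = exp(beta + zq * se)),
         p_value = max(2 * stats::pnorm(-abs(zstat)), .Machine$double.xmin),
         score_chisq = score_chisq,
         score_p = stats::pchisq(score_chisq, 1, lower.tail = FALSE),
         ties_method = ties, n = length(time), n_events = sum(event),
         loglik = lui$loglik, conf_level = conf_level),
    class = "nk_cox"
  )
}

#' @export
print.nk_cox <- function(x, ...) {
  cat(sprintf(
    "<nk_cox (%s ties): HR = %.3f [%.3f, %.3f], p = %.3g, n = %d (%d events)>\n",
    x$ties_method, x$hazard_ratio, x$ci95[["low"]], x$ci95[["high"]],
    x$p_value, x$n, x$n_events))
  invisible(x)
}

#' Optimal-cutpoint univariate survival screen
#'
#' For every immune variable x compartment x endpoint: dichotomize the
#' covariate at its maximally selected cutpoint, then estimate the Cox
#' hazard ratio of the high (`value > cutpoint`) versus low group. p-values
#' are unadjusted; combinations whose cutpoint search or Cox fit fails are
#' recorded with the error message and the screen continues.
#'
#' @param data Per-patient analysis table ([cohort_table()] output) with
#'   `os_months, os_event, pfs_months, pfs_event`.
#' @param variables Subset names (default: the main immune subsets).
#' @param compartments Compartments to screen (columns
#'   `<variable>_<compartment>` must exist).
#' @param endpoints Any of `"OS"`, `"PFS"`.
#' @param minprop Minimum group fraction for the cutpoint search.
#' @param ties Cox tie handling.
#' @param alpha Flagging level (unadjusted).
#' @return An `nk_screen` tibble: `endpoint, variable, compartment,
#'   cutpoint, n_low, n_high, hr, ci_low, ci_high, p, flag, error`.
#' @export
survival_screen <- function(data,
                            variables = c("T_cell", "B_cell", "CD57_NK_cell",
                                          "macrophage", "CD57_T_cell",
                                          "CD16_NK_cell", "NKG2A_NK_cell"),
                            compartments = c("tumoral", "stromal", "total"),
                            endpoints = c("OS", "PFS"),
                            minprop = 0.1, ties = "efron", alpha = 0.05) {
  endpoints <- match.arg(endpoints, c("OS", "PFS"), several.ok = TRUE)
  rows <- list()
  for (ep in endpoints) {
    tcol <- if (ep == "OS") "os_months" else "pfs_months"
    ecol <- if (ep == "OS") "os_event" else "pfs_event"
    need_columns(data, c(tcol, ecol), "analysis table")
    for (v in variables) {
      for (comp in compartments) {
        col <- paste(v, comp, sep = "_")
        row <- tibble::tibble(endpoint = ep, variable = v, compartment = comp,
                              cutpoint = NA_real_, n_low = NA_integer_,
                              n_high = NA_integer_, hr = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_, flag = FALSE, error = NA_character_)
        res <- tryCatch({
          need_columns(data, col, "analysis table")
          keep <- is.finite(data[[col]]) & is.finite(data[[tcol]]) &
            !is.na(data[[ecol]])
          tt <- data[[tcol]][keep]; ee <- data[[ecol]][keep]
          xx <- data[[col]][keep]
          cut <- max_sel_cutpoint(tt, ee, xx, minprop = minprop)
          high <- as.numeric(xx > cut$cutpoint)
          cox <- cox_univariate(tt, ee, high, ties = ties)
          row$cutpoint <- cut$cutpoint
          row$n_low <- cut$n_low; row$n_high <- cut$n_high
          row$hr <- cox$hazard_ratio
          row$ci_low <- cox$ci95[["low"]]; row$ci_high <- cox$ci95[["high"]]
          row$p <- cox$p_value
          row$flag <- cox$p_value < alpha
          row
        }, nkmihc_error = function(e) {
          row$error <- conditionMessage(e)
          row
        })
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(endpoint = character(), variable = character(),
                          compartment = character(), cutpoint = numeric(),
                          n_low = integer(), n_high = integer(),
                          hr = numeric(), ci_low = numeric(),
                          ci_high = numeric(), p = numeric(),
                          flag = logical(), error = character())
  }
  class(out) <- c("nk_screen", class(out))
  out
}
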
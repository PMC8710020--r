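# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn cox_univariate One row per term: estimate (log hazard),
#'   std.error, statistic, p.value, hazard ratio and CI.
#' @param x An `nk_cox` object.
#' @param ... Unused.
#' @export
tidy.nk_cox <- function(x, ...) {
  tibble::tibble(
    term = "x", estimate = x$log_hazard, std.error = x$standard_error,
    statistic = x$log_hazard / x$standard_error, p.value = x$p_value,
    hazard.ratio = x$hazard_ratio,
    conf.low = x$ci95[["low"]], conf.high = x$ci95[["high"]]
  )
}

#' @describeIn cox_univariate One-row model summary.
#' @export
glance.nk_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n.events = x$n_events, logLik = x$loglik,
                 score.chisq = x$score_chisq, score.p = x$score_p,
                 ties = x$ties_method)
}

#' @describeIn max_sel_cutpoint The candidate scan as a tibble.
#' @param x An `nk_cutpoint` object.
#' @param ... Unused.
#' @export
tidy.nk_cutpoint <- function(x, ...) x$scan

#' @describeIn max_sel_cutpoint One-row summary of the selected cutpoint.
#' @export
glance.nk_cutpoint <- function(x, ...) {
  tibble::tibble(cutpoint = x$cutpoint,
                 standardized.statistic = x$standardized_statistic,
                 n.low = x$n_low, n.high = x$n_high, minprop = x$minprop,
                 n = x$n)
}

#' @describeIn km_curve The step table as a tibble.
#' @param x An `nk_km` object.
#' @param ... Unused.
#' @export
tidy.nk_km <- function(x, ...) x$steps

#' @describeIn km_curve One-row summary (n, events, median).
#' @export
glance.nk_km <- function(x, ...) {
  tibble::tibble(n = x$n, n.events = x$n_events, median = x$median)
}
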
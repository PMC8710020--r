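# Non-survival statistics: Spearman correlation, Welch t, OLS.

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the p-value uses the t approximation with n - 2 degrees of freedom, or an
#' exact permutation distribution when `exact = TRUE` (n <= 10). Missing
#' values are dropped pairwise.
#'
#' @param x,y Numeric vectors of equal length (>= 4 complete pairs).
#' @param exact Exact permutation p (only for n <= 10).
#' @return Tibble `rho, p_value, n, method`.
#' @export
#' @examples
#' spearman_cor(1:10, (1:10)^3)
spearman_cor <- function(x, y, exact = FALSE) {
  assert_that(length(x) == length(y), "x and y must have equal length",
              "nkmihc_schema_error")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 4, "need >= 4 complete pairs", "nkmihc_stat_error")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("undefined correlation: a variable has zero rank variance",
          class = c("nkmihc_stat_error", "nkmihc_error"))
  }
  rho <- stats::cor(rx, ry)
  if (exact) {
    assert_that(n <= 10, "exact permutation p only for n <= 10",
                "nkmihc_stat_error")
    perms <- permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(min(p, 1), .Machine$double.xmin)
    method <- "t-approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' All-pairs Spearman correlation matrix
#'
#' @param data Analysis tibble.
#' @param variables Character vector (>= 2) of numeric columns to correlate.
#' @param alpha Significance flag level (unadjusted; default 0.05).
#' @return Long tibble `var1, var2, rho, p, n, significant`; symmetric with
#'   unit diagonal. Pairs with undefined correlation get `NA` entries.
#' @export
correlation_matrix <- function(data, variables, alpha = 0.05) {
  assert_that(length(variables) >= 2, "need >= 2 variables",
              "nkmihc_stat_error")
  need_columns(data, variables, "analysis table")
  grid <- expand.grid(var1 = variables, var2 = variables,
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(var1, var2) {
    if (var1 == var2) {
      n <- sum(is.finite(data[[var1]]))
      return(tibble::tibble(var1, var2, rho = 1, p = NA_real_, n = n))
    }
    res <- tryCatch(spearman_cor(data[[var1]], data[[var2]]),
                    nkmihc_stat_error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(var1, var2, rho = NA_real_, p = NA_real_, n = NA_integer_)
    } else {
      tibble::tibble(var1, var2, rho = res$rho, p = res$p_value, n = res$n)
    }
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = !is.na(.data$p) & .data$p < alpha)
  class(out) <- c("nk_corr_matrix", class(out))
  out
}

#' Welch two-sample t-test between groups
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector with exactly two levels (each n >= 2).
#' @return Tibble `variable` means per group, `t_statistic,
#'   degrees_of_freedom, p_value, group1, group2, n1, n2`.
#' @export
welch_t <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  lev <- sort(unique(groups))
  assert_that(length(lev) == 2, "need exactly two groups",
              "nkmihc_stat_error")
  g1 <- values[groups == lev[1]]; g2 <- values[groups == lev[2]]
  assert_that(length(g1) >= 2 && length(g2) >= 2,
              "each group needs n >= 2", "nkmihc_stat_error")
  if (stats::var(g1) + stats::var(g2) == 0) {
    if (mean(g1) == mean(g2)) {
      return(tibble::tibble(group1 = lev[1], group2 = lev[2],
                            mean1 = mean(g1), mean2 = mean(g2),
                            t_statistic = 0, degrees_of_freedom = NA_real_,
                            p_value = 1, n1 = length(g1), n2 = length(g2)))
    }
    abort("untestable: zero variance in both groups",
          class = c("nkmihc_stat_error", "nkmihc_error"))
  }
  tt <- stats::t.test(g1, g2, var.equal = FALSE)
  tibble::tibble(group1 = lev[1], group2 = lev[2],
                 mean1 = mean(g1), mean2 = mean(g2),
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 n1 = length(g1), n2 = length(g2))
}

#' Compare a set of variables across a two-level stratum
#'
#' Runs [welch_t()] for each variable against `stratum`; untestable
#' variables are reported with `NA` statistics rather than aborting the rest.
#'
#' @param data Analysis tibble.
#' @param variables Numeric columns to compare.
#' @param stratum Name of the two-level grouping column.
#' @return Tibble `variable, stratum, group1, group2, t, df, p`.
#' @export
group_comparisons <- function(data, variables, stratum) {
  need_columns(data, c(variables, stratum), "analysis table")
  purrr::map_dfr(variables, function(v) {
    res <- tryCatch(welch_t(data[[v]], data[[stratum]]),
                    nkmihc_stat_error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(variable = v, stratum = stratum,
                     group1 = NA_character_, group2 = NA_character_,
                     t = NA_real_, df = NA_real_, p = NA_real_)
    } else {
      tibble::tibble(variable = v, stratum = stratum,
                     group1 = res$group1, group2 = res$group2,
                     t = res$t_statistic, df = res$degrees_of_freedom,
                     p = res$p_value)
    }
  })
}

#' Simple least-squares linear fit
#'
#' @param x,y Numeric vectors (n >= 3; x non-constant).
#' @return Tibble `slope, intercept, r_squared, p_value, n` (slope t-test
#'   with n - 2 df).
#' @export
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "need >= 3 complete pairs", "nkmihc_stat_error")
  if (stats::sd(x) == 0) {
    abort("singular fit: x is constant",
          class = c("nkmihc_stat_error", "nkmihc_error"))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate inputs
  p <- if (nrow(sm$coefficients) >= 2 && is.finite(sm$coefficients[2, 4])) {
    sm$coefficients[2, 4]
  } else NA_real_
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, p_value = p, n = length(x))
}
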
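# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_tile geom_point
#'   geom_errorbarh geom_col geom_hline geom_vline scale_fill_gradient2 labs
#'   theme_minimal facet_wrap coord_cartesian
#' @export
ggplot2::autoplot

#' @describeIn km_curve Kaplan-Meier step plot.
#' @param object An `nk_km` object.
#' @export
autoplot.nk_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object$steps[, c("time", "survival")]
  )
  ggplot(df, aes(x = .data$time, y = .data$survival)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Time (months)", y = "Survival probability") +
    theme_minimal()
}

#' @describeIn max_sel_cutpoint Standardized log-rank statistic across all
#'   admissible cutpoints, with the selected one marked.
#' @param object An `nk_cutpoint` object.
#' @export
autoplot.nk_cutpoint <- function(object, ...) {
  ggplot(object$scan, aes(x = .data$cutpoint, y = abs(.data$z))) +
    geom_step() +
    geom_vline(xintercept = object$cutpoint, linetype = 2) +
    labs(x = "Candidate cutpoint", y = "|standardized log-rank statistic|") +
    theme_minimal()
}

#' @describeIn survival_screen Forest plot of hazard ratios per variable x
#'   compartment, faceted by endpoint.
#' @param object An `nk_screen` tibble.
#' @param ... Unused.
#' @export
autoplot.nk_screen <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$hr)) |>
    dplyr::mutate(label = paste(.data$variable, .data$compartment))
  ggplot(df, aes(x = .data$hr, y = .data$label, colour = .data$flag)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    facet_wrap(~endpoint) +
    labs(x = "Hazard ratio (high vs low)", y = NULL, colour = "p < alpha") +
    theme_minimal()
}

#' @describeIn correlation_matrix Correlation heatmap with significance
#'   marks.
#' @param object An `nk_corr_matrix` tibble.
#' @param ... Unused.
#' @export
autoplot.nk_corr_matrix <- function(object, ...) {
  ggplot(object, aes(x = .data$var1, y = .data$var2, fill = .data$rho)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = ifelse(.data$significant, "*", "")),
                       size = 5) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman rho") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Composition bar chart of immune phenotypes per core
#'
#' @param core_quants Named list from [quantify_cohort()].
#' @return A ggplot: stacked per-core CD45+ composition fractions.
#' @export
plot_composition <- function(core_quants) {
  df <- dplyr::bind_rows(lapply(core_quants, function(q)
    dplyr::mutate(q$composition, core_id = q$core_id))) |>
    dplyr::filter(.data$denominator == "CD45+")
  ggplot(df, aes(x = .data$core_id, y = .data$fraction,
                 fill = .data$variable)) +
    geom_col() +
    labs(x = NULL, y = "Fraction of CD45+ cells", fill = "Phenotype") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
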
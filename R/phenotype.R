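# Marker thresholding and hierarchical lineage gating.

#' Construct a marker panel of per-channel thresholds
#'
#' @param thresholds Named numeric vector of positivity cut-offs (intensity
#'   units), one per channel.
#' @param methods Named character vector (`"distribution"` or `"manual"`) per
#'   channel; defaults to `"manual"` for all.
#' @return A `marker_panel` object.
#' @export
marker_panel <- function(thresholds, methods = NULL) {
  assert_that(length(thresholds) > 0 && !is.null(names(thresholds)),
              "thresholds must be a named numeric vector",
              "nkmihc_config_error")
  assert_that(all(is.finite(thresholds)) && all(thresholds >= 0),
              "thresholds must be finite and >= 0", "nkmihc_config_error")
  if (is.null(methods)) {
    methods <- setNames(rep("manual", length(thresholds)), names(thresholds))
  }
  structure(list(channels = names(thresholds),
                 thresholds = thresholds,
                 methods = methods[names(thresholds)]),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>\n")
  for (ch in x$channels) {
    cat(sprintf("  %-6s %8.4f  (%s)\n", ch, x$thresholds[[ch]],
                x$methods[[ch]]))
  }
  invisible(x)
}

#' Derive a positivity threshold from an intensity distribution
#'
#' For `method = "distribution"`, fits a two-component Gaussian mixture with
#' unequal variances to the log intensities (mclust EM) and returns the
#' intensity at which the posterior probability of the positive component is
#' 0.5, i.e. the decision boundary between the negative and positive stain
#' populations. For `method = "manual"` the supplied value is returned
#' unchanged.
#'
#' @param intensities Non-negative intensity vector (>= 50 finite values for
#'   the distribution method).
#' @param method `"distribution"` or `"manual"`.
#' @param value Manual threshold (required when `method = "manual"`).
#' @param seed Seed controlling the EM initialisation subsample on large
#'   inputs.
#' @return A single numeric threshold.
#' @export
#' @examples
#' x <- c(exp(rnorm(200, 0, 0.3)), exp(rnorm(200, 2.5, 0.3)))
#' derive_threshold(x)
derive_threshold <- function(intensities, method = c("distribution", "manual"),
                             value = NULL, seed = 1L) {
  method <- match.arg(method)
  if (method == "manual") {
    assert_that(is.numeric(value) && length(value) == 1 && is.finite(value),
                "manual method requires a single finite threshold value",
                "nkmihc_config_error")
    return(as.numeric(value))
  }
  x <- intensities[is.finite(intensities)]
  assert_that(length(x) >= 50,
              "distribution method needs >= 50 finite intensities",
              "nkmihc_threshold_error")
  if (stats::sd(x) == 0) {
    abort("threshold underivable: zero-variance intensities (supply a manual threshold)",
          class = c("nkmihc_threshold_error", "nkmihc_error"))
  }
  lx <- log(pmax(x, 1e-8))
  init <- NULL
  if (length(lx) > 2000) {
    init <- list(subset = with_seed(seed, sample(length(lx), 2000)))
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(lx, G = 2, modelNames = "V",
                                    initialization = init, verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit) || is.null(fit$parameters)) {
    abort("threshold underivable: mixture fit failed (supply a manual threshold)",
          class = c("nkmihc_threshold_error", "nkmihc_error"))
  }
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  w <- fit$parameters$pro
  lo <- which.min(mu); hi <- which.max(mu)
  sep <- (mu[hi] - mu[lo]) / max(sg)
  if (sep < 2 || min(w) < 0.01) {
    abort("threshold underivable: intensity distribution is not clearly bimodal (supply a manual threshold)",
          class = c("nkmihc_threshold_error", "nkmihc_error"))
  }
  g <- function(z) w[lo] * stats::dnorm(z, mu[lo], sg[lo]) -
    w[hi] * stats::dnorm(z, mu[hi], sg[hi])
  boundary <- if (g(mu[lo]) > 0 && g(mu[hi]) < 0) {
    stats::uniroot(g, c(mu[lo], mu[hi]), tol = 1e-10)$root
  } else {
    (mu[lo] + mu[hi]) / 2
  }
  exp(boundary)
}

#' Derive thresholds for many channels at once
#'
#' @param cells Cells tibble carrying one intensity column per channel.
#' @param channels Channels to threshold (default: the full panel).
#' @param method Single method or named character vector per channel.
#' @param manual Named numeric vector of manual thresholds for channels with
#'   `method = "manual"`.
#' @param seed Seed forwarded to [derive_threshold()].
#' @return A `marker_panel`.
#' @export
derive_panel <- function(cells, channels = panel_channels(),
                         method = "distribution", manual = NULL, seed = 1L) {
  if (length(method) == 1) {
    method <- setNames(rep(method, length(channels)), channels)
  }
  thr <- vapply(channels, function(ch) {
    need_columns(cells, ch, "cells table")
    derive_threshold(cells[[ch]], method = method[[ch]],
                     value = manual[[ch]], seed = derive_seed(seed, match(ch, channels)))
  }, numeric(1))
  marker_panel(thr, method)
}

#' Call per-channel positivity against a marker panel
#'
#' A cell is positive for a channel iff its intensity is strictly greater
#' than the channel threshold (ties are negative).
#'
#' @param cells Cells tibble with intensity columns.
#' @param panel A [marker_panel()].
#' @return Tibble with `cell_id` and one logical column per panel channel.
#' @export
call_positivity <- function(cells, panel) {
  missing <- setdiff(panel$channels, names(cells))
  if (length(missing) > 0) {
    abort(sprintf("cells table is missing intensity column(s): %s",
                  paste(missing, collapse = ", ")),
          class = c("nkmihc_schema_error", "nkmihc_error"))
  }
  out <- tibble::tibble(cell_id = cells$cell_id)
  for (ch in panel$channels) {
    out[[ch]] <- cells[[ch]] > panel$thresholds[[ch]]
  }
  out
}

#' Assign immune phenotypes by the ordered lineage cascade
#'
#' CD45+ cells are resolved in order CD3 (T cell), CD20 (B cell), CD57
#' (CD57+ NK cell), CD68 (macrophage), else other immune. CD45- cells are
#' tumor cells when CK+, otherwise non-immune stroma. Cells positive for
#' more than one lineage marker are resolved by cascade order and flagged
#' `"multilineage"`.
#'
#' @param positivity Tibble from [call_positivity()] containing at least the
#'   CD45, CD3, CD20, CD57, CD68 and CK calls.
#' @return Tibble `cell_id, phenotype, cd57, flags`.
#' @export
assign_phenotype <- function(positivity) {
  need_columns(positivity, gating_channels(), "positivity table")
  p <- positivity
  phenotype <- dplyr::case_when(
    p$CD45 & p$CD3 ~ "T_cell",
    p$CD45 & p$CD20 ~ "B_cell",
    p$CD45 & p$CD57 ~ "NK_cell",
    p$CD45 & p$CD68 ~ "macrophage",
    p$CD45 ~ "other_immune",
    p$CK ~ "tumor_cell",
    TRUE ~ "other_nonimmune"
  )
  n_lineage <- p$CD3 + p$CD20 + p$CD68 +
    (p$CD57 & !p$CD3)   # CD57 on T cells is expected, not a conflict
  flags <- dplyr::case_when(
    p$CD45 & n_lineage > 1 ~ "multilineage",
    TRUE ~ ""
  )
  tibble::tibble(cell_id = p$cell_id, phenotype = phenotype,
                 cd57 = p$CD57, flags = flags)
}

#' Attach CD16/NKG2A receptor status
#'
#' Receptor booleans are copied from the positivity calls for every cell;
#' downstream subset tallies only count them on immune phenotypes.
#'
#' @param positivity Tibble from [call_positivity()] with CD16 and NKG2A
#'   columns.
#' @param phenotypes Tibble from [assign_phenotype()].
#' @return `phenotypes` with `cd16` and `nkg2a` columns appended.
#' @export
assign_receptor_status <- function(positivity, phenotypes) {
  need_columns(positivity, c("CD16", "NKG2A"), "positivity table")
  dplyr::left_join(
    phenotypes,
    tibble::tibble(cell_id = positivity$cell_id,
                   cd16 = positivity$CD16, nkg2a = positivity$NKG2A),
    by = "cell_id"
  )
}

#' Gate a cells table end to end
#'
#' Convenience wrapper: positivity calls, lineage cascade and receptor
#' status in one step.
#'
#' @param cells Cells tibble with intensity columns.
#' @param panel A [marker_panel()] covering at least the gating channels and
#'   CD16/NKG2A/HLAE.
#' @return `cells` with per-channel positivity columns (prefixed `pos_`) and
#'   `phenotype, cd57, cd16, nkg2a, flags` appended.
#' @export
#' @examples
#' b <- simulate_cohort(sim_config(n_patients = 2, cells_per_core_mean = 300))
#' pan <- derive_panel(b$cells, c("CD45", "CD3", "CD20", "CD57", "CD68",
#'                                "CK", "CD16", "NKG2A", "HLAE"))
#' gated <- gate_cells(b$cells, pan)
#' table(gated$phenotype)
gate_cells <- function(cells, panel) {
  pos <- call_positivity(cells, panel)
  ph <- assign_phenotype(pos)
  ph <- assign_receptor_status(pos, ph)
  pos_cols <- pos[, panel$channels, drop = FALSE]
  names(pos_cols) <- paste0("pos_", panel$channels)
  dplyr::bind_cols(cells, pos_cols) |>
    dplyr::left_join(ph, by = "cell_id")
}
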
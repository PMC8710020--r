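# End-to-end orchestration: simulate -> gate -> quantify -> associate ->
# screen, with structured logging and a JSON run manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all stage files.
#' @param simulate A [sim_config()] to generate the cohort, or `NULL` to read
#'   an existing fixture from `input_dir`.
#' @param input_dir Directory holding `cells.csv`, `masks.geojson`,
#'   `clinical.csv` when `simulate` is `NULL`.
#' @param gate_channels Channels gated by the pipeline.
#' @param threshold_method `"distribution"` or `"manual"` (single value or
#'   named per channel).
#' @param manual_thresholds Named numeric vector; used for channels with
#'   manual method and as fallback when a distribution fit is underivable.
#' @param corr_variables Density columns entering the correlation stage
#'   (default: main immune densities, tumoral, plus HLA-E+ tumor density).
#' @param minprop,ties,alpha Survival-screen settings (see
#'   [survival_screen()]).
#' @param seed Seed for threshold derivation subsampling.
#' @param stages Stages to run, in order.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            simulate = NULL,
                            input_dir = NULL,
                            gate_channels = c("CD45", "CD3", "CD20", "CD57",
                                              "CD68", "CK", "CD16", "NKG2A",
                                              "HLAE"),
                            threshold_method = "distribution",
                            manual_thresholds = NULL,
                            corr_variables = c("T_cell_tumoral",
                                               "B_cell_tumoral",
                                               "CD57_NK_cell_tumoral",
                                               "macrophage_tumoral",
                                               "HLAE_tumor_tumoral"),
                            minprop = 0.1, ties = "efron", alpha = 0.05,
                            seed = 1L,
                            stages = c("simulate", "gate", "quantify",
                                       "associate", "screen")) {
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)",
              "nkmihc_config_error")
  assert_that(!is.null(simulate) || !is.null(input_dir),
              "either a sim_config or an input_dir is required",
              "nkmihc_config_error")
  structure(list(out_dir = out_dir, simulate = simulate,
                 input_dir = input_dir, gate_channels = gate_channels,
                 threshold_method = threshold_method,
                 manual_thresholds = manual_thresholds,
                 corr_variables = corr_variables,
                 minprop = minprop, ties = ties, alpha = alpha,
                 seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

log_stage <- function(stage, msg, log_path = NULL) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
}

#' Validate pipeline input files
#'
#' Schema checks on the cells CSV, the GeoJSON masks and the clinical CSV.
#' Problems are reported per file; no error aborts the other checks.
#'
#' @param paths Named list/vector with any of `cells`, `masks`, `clinical`.
#' @return Tibble `file, error` (zero rows when everything is well-formed).
#' @export
validate_inputs <- function(paths) {
  errs <- list()
  add <- function(file, msg) {
    errs[[length(errs) + 1]] <<- tibble::tibble(file = file, error = msg)
  }
  if (!is.null(paths$cells)) {
    tryCatch(invisible(read_cells(paths$cells)),
             error = function(e) add(paths$cells, conditionMessage(e)))
  }
  if (!is.null(paths$clinical)) {
    tryCatch(invisible(read_clinical(paths$clinical)),
             error = function(e) add(paths$clinical, conditionMessage(e)))
  }
  if (!is.null(paths$masks)) {
    tryCatch({
      masks <- read_masks(paths$masks)
      for (m in masks) {
        for (poly in m$polygons) {
          if (!is_simple_polygon(poly)) {
            add(paths$masks,
                sprintf("core %s: self-intersecting polygon", m$core_id))
          }
        }
      }
    }, error = function(e) add(paths$masks, conditionMessage(e)))
  }
  if (length(errs) == 0) {
    tibble::tibble(file = character(), error = character())
  } else {
    dplyr::bind_rows(errs)
  }
}

# Proper-intersection test between segments p1-p2 and p3-p4.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_simple_polygon <- function(poly) {
  k <- nrow(poly)
  if (k < 3) return(FALSE)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i + 1 || (i == 1 && j == k)) next
      if (segments_cross(poly[i, ], poly[i %% k + 1, ],
                         poly[j, ], poly[j %% k + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Run the full quantification pipeline
#'
#' Executes the configured stages in order (simulate, gate, quantify,
#' associate, screen), writing each stage's CSV outputs plus a JSON run
#' manifest (package version, seed, config hash, per-stage row counts and
#' status) under `config$out_dir`. A stage failure halts downstream stages;
#' outputs of completed stages are retained and the manifest records the
#' failure point. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with the in-memory stage results and the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config", "nkmihc_config_error")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  manifest <- list(
    package = "nkmihc",
    version = as.character(utils::packageVersion("nkmihc")),
    seed = config$seed,
    config_hash = fnv1a(jsonlite::toJSON(
      config[setdiff(names(config),
                     c("simulate", "out_dir", "input_dir"))],
      auto_unbox = TRUE, force = TRUE)),
    stages = list()
  )
  results <- list()
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed || !(name %in% config$stages)) return(invisible(NULL))
    log_stage(name, "start", log_path)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      log_stage(name, paste("FAILED:", conditionMessage(res)), log_path)
    } else {
      manifest$stages[[name]] <<- c(list(status = "ok"), res$counts)
      results[[name]] <<- res$value
      log_stage(name, paste(names(res$counts), unlist(res$counts),
                            sep = "=", collapse = " "), log_path)
    }
    invisible(NULL)
  }

  fixture_dir <- config$input_dir
  run_stage("simulate", function() {
    bundle <- simulate_cohort(config$simulate)
    fixture_dir <<- file.path(out, "fixture")
    write_fixture(bundle, fixture_dir)
    list(value = bundle,
         counts = list(cells = nrow(bundle$cells),
                       patients = nrow(bundle$clinical)))
  })

  run_stage("gate", function() {
    cells <- read_cells(file.path(fixture_dir, "cells.csv"))
    panel <- derive_panel_with_fallback(cells, config)
    gated <- gate_cells(cells, panel)
    write_thresholds(panel, file.path(out, "thresholds.csv"))
    readr::write_csv(gated, file.path(out, "gated_cells.csv"),
                     progress = FALSE)
    list(value = list(panel = panel, gated = gated),
         counts = list(cells = nrow(gated),
                       immune = sum(gated$phenotype %in% immune_phenotypes())))
  })

  run_stage("quantify", function() {
    masks <- read_masks(file.path(fixture_dir, "masks.geojson"))
    clinical <- read_clinical(file.path(fixture_dir, "clinical.csv"))
    gated <- assign_compartments(results$gate$gated, masks)
    quants <- quantify_cohort(gated, masks)
    long <- dplyr::bind_rows(lapply(quants, function(q)
      dplyr::mutate(q$quant, core_id = q$core_id, .before = 1)))
    readr::write_csv(long, file.path(out, "core_quant.csv"), progress = FALSE)
    analysis <- cohort_table(quants, clinical)
    readr::write_csv(analysis, file.path(out, "analysis_table.csv"),
                     progress = FALSE)
    list(value = list(quants = quants, analysis = analysis),
         counts = list(cores = length(quants), analysis_rows = nrow(analysis)))
  })

  run_stage("associate", function() {
    analysis <- results$quantify$analysis
    vars <- intersect(config$corr_variables, names(analysis))
    corr <- correlation_matrix(analysis, vars, alpha = config$alpha)
    readr::write_csv(corr, file.path(out, "correlations.csv"),
                     progress = FALSE)
    comp <- group_comparisons(analysis,
                              intersect(c("T_cell_total", "B_cell_total",
                                          "CD57_NK_cell_total",
                                          "macrophage_total"),
                                        names(analysis)),
                              "stage")
    readr::write_csv(comp, file.path(out, "group_comparisons.csv"),
                     progress = FALSE)
    list(value = list(correlations = corr, comparisons = comp),
         counts = list(pairs = nrow(corr)))
  })

  run_stage("screen", function() {
    analysis <- results$quantify$analysis
    scr <- survival_screen(analysis, minprop = config$minprop,
                           ties = config$ties, alpha = config$alpha)
    readr::write_csv(scr, file.path(out, "survival_screen.csv"),
                     progress = FALSE)
    list(value = scr,
         counts = list(combinations = nrow(scr),
                       flagged = sum(scr$flag, na.rm = TRUE)))
  })

  manifest$status <- if (failed) "failed" else "ok"
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest))
}

# Distribution thresholds with manual fallback per channel.
derive_panel_with_fallback <- function(cells, config) {
  method <- config$threshold_method
  chans <- config$gate_channels
  if (length(method) == 1) method <- setNames(rep(method, length(chans)), chans)
  thr <- numeric(0); used <- character(0)
  for (ch in chans) {
    if (identical(method[[ch]], "manual")) {
      thr[ch] <- derive_threshold(cells[[ch]], "manual",
                                  value = config$manual_thresholds[[ch]])
      used[ch] <- "manual"
    } else {
      t <- tryCatch(
        derive_threshold(cells[[ch]], "distribution",
                         seed = derive_seed(config$seed, match(ch, chans))),
        nkmihc_threshold_error = function(e) {
          if (!is.null(config$manual_thresholds[[ch]])) {
            NA_real_
          } else {
            abort(sprintf("channel %s: %s", ch, conditionMessage(e)),
                  class = c("nkmihc_threshold_error", "nkmihc_error"))
          }
        })
      if (is.na(t)) {
        thr[ch] <- config$manual_thresholds[[ch]]
        used[ch] <- "manual"
      } else {
        thr[ch] <- t
        used[ch] <- "distribution"
      }
    }
  }
  marker_panel(thr, used)
}
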
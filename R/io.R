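# Readers/writers for the pipeline's on-disk formats: cells CSV, tumor-mask
# GeoJSON, clinical CSV, threshold CSV and the simulator config (JSON).

cells_csv_columns <- function() {
  c("cell_id", "core_id", "x_um", "y_um", panel_channels())
}

clinical_csv_columns <- function() {
  c("patient_id", "core_id", "os_months", "os_event", "pfs_months",
    "pfs_event", "stage", "ebv_ish", "bat26", "bat25", "d5s346", "d17s250",
    "d2s123", "ecad_altered", "p53_positive")
}

#' Read a segmented-cells table
#'
#' @param path CSV with columns `cell_id, core_id, x_um, y_um` and one
#'   intensity column per panel channel.
#' @return Tibble of cells.
#' @export
read_cells <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need_columns(df, cells_csv_columns(), sprintf("cells file '%s'", path))
  df
}

#' Read a clinical table
#'
#' @param path CSV with per-patient outcomes, stage, EBV ISH, the five MSI
#'   marker instability flags and E-cadherin/p53 IHC calls.
#' @return Tibble of clinical records.
#' @export
read_clinical <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need_columns(df, clinical_csv_columns(), sprintf("clinical file '%s'", path))
  df
}

#' Write tumor-region masks as GeoJSON
#'
#' One Polygon feature per tumor region with properties `core_id` and
#' `core_diameter_um`; coordinates in micrometres in the cells' frame.
#'
#' @param masks Named list of `region_mask` objects.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  features <- list()
  for (m in masks) {
    for (poly in m$polygons) {
      ring <- rbind(poly, poly[1, , drop = FALSE])   # closed ring
      features[[length(features) + 1]] <- list(
        type = "Feature",
        properties = list(core_id = m$core_id,
                          core_diameter_um = m$core_diameter_um),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(i) ring[i, ])))
      )
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tumor-region masks from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygon features carrying
#'   `core_id` (and optionally `core_diameter_um`) properties.
#' @return Named list of `region_mask` objects, one per core.
#' @export
read_masks <- function(path) {
  fc <- jsonlite::read_json(path)
  assert_that(identical(fc$type, "FeatureCollection"),
              sprintf("'%s' is not a GeoJSON FeatureCollection", path),
              "nkmihc_schema_error")
  polys <- list()
  diam <- list()
  for (f in fc$features) {
    cid <- f$properties$core_id
    assert_that(!is.null(cid), "mask feature lacks a core_id property",
                "nkmihc_schema_error")
    assert_that(identical(f$geometry$type, "Polygon"),
                sprintf("core %s: only Polygon geometries are supported", cid),
                "nkmihc_schema_error")
    ring <- f$geometry$coordinates[[1]]
    mat <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex
    if (nrow(mat) > 1 && all(mat[1, ] == mat[nrow(mat), ])) {
      mat <- mat[-nrow(mat), , drop = FALSE]
    }
    polys[[cid]] <- c(polys[[cid]], list(mat))
    if (!is.null(f$properties$core_diameter_um)) {
      diam[[cid]] <- f$properties$core_diameter_um
    }
  }
  out <- lapply(names(polys), function(cid) {
    d <- diam[[cid]]
    if (is.null(d)) {
      # fall back to the bounding box of the union of polygons
      allxy <- do.call(rbind, polys[[cid]])
      d <- max(diff(range(allxy[, 1])), diff(range(allxy[, 2])))
    }
    new_region_mask(cid, polys[[cid]], d)
  })
  setNames(out, names(polys))
}

#' Write a cohort bundle to a fixture directory
#'
#' Emits `cells.csv`, `masks.geojson`, `clinical.csv`, `truth.csv` (generator
#' labels, kept apart from pipeline inputs), `truth_clinical.csv` and
#' `config.json`. The files round-trip losslessly through [read_fixture()].
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    assert_that(ok, sprintf("cannot create directory '%s'", dir),
                "nkmihc_io_error")
  }
  readr::write_csv(bundle$cells, file.path(dir, "cells.csv"), progress = FALSE)
  write_masks(bundle$masks, file.path(dir, "masks.geojson"))
  readr::write_csv(bundle$clinical, file.path(dir, "clinical.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$truth, file.path(dir, "truth.csv"), progress = FALSE)
  readr::write_csv(bundle$truth_clinical, file.path(dir, "truth_clinical.csv"),
                   progress = FALSE)
  write_sim_config(bundle$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Read a fixture directory back into a cohort bundle
#'
#' @param dir Directory written by [write_fixture()].
#' @return A `cohort_bundle`.
#' @export
read_fixture <- function(dir) {
  structure(
    list(
      cells = read_cells(file.path(dir, "cells.csv")),
      masks = read_masks(file.path(dir, "masks.geojson")),
      clinical = read_clinical(file.path(dir, "clinical.csv")),
      truth = readr::read_csv(file.path(dir, "truth.csv"),
                              show_col_types = FALSE, progress = FALSE),
      truth_clinical = readr::read_csv(file.path(dir, "truth_clinical.csv"),
                                       show_col_types = FALSE,
                                       progress = FALSE),
      config = read_sim_config(file.path(dir, "config.json"))
    ),
    class = "cohort_bundle"
  )
}

#' @rdname write_fixture
#' @param config A [sim_config()].
#' @param path JSON path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$composition <- as.list(x$composition)
  x$subtype_frequencies <- as.list(x$subtype_frequencies)
  x$receptor_rates <- lapply(x$receptor_rates, as.list)
  x$hlae_model$link <- as.list(x$hlae_model$link)
  x$survival_model$coefficients <- as.list(x$survival_model$coefficients)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_fixture
#' @param path JSON path written by [write_sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(l) vapply(l, as.numeric, numeric(1))
  sim_config(
    n_patients = x$n_patients,
    cells_per_core_mean = x$cells_per_core_mean,
    core_diameter_um = x$core_diameter_um,
    tumor_area_fraction = x$tumor_area_fraction,
    composition = num(x$composition),
    cd57_rate_T = x$cd57_rate_T,
    receptor_rates = lapply(x$receptor_rates, num),
    intensity_model = lapply(x$intensity_model, function(m)
      lapply(m, as.numeric)),
    hlae_model = list(base_rate = as.numeric(x$hlae_model$base_rate),
                      link = num(x$hlae_model$link)),
    survival_model = c(lapply(x$survival_model[setdiff(names(x$survival_model),
                                                       "coefficients")],
                              as.numeric),
                       list(coefficients = num(x$survival_model$coefficients))),
    subtype_frequencies = num(x$subtype_frequencies),
    seed = x$seed
  )
}

#' Read/write derived marker thresholds
#'
#' @param panel A `marker_panel` (see [derive_panel()]).
#' @param path CSV path with columns `channel,threshold,method`.
#' @return For `write_thresholds`, `path` invisibly; for `read_thresholds`,
#'   a `marker_panel`.
#' @export
write_thresholds <- function(panel, path) {
  readr::write_csv(
    tibble::tibble(channel = panel$channels,
                   threshold = unname(panel$thresholds[panel$channels]),
                   method = unname(panel$methods[panel$channels])),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need_columns(df, c("channel", "threshold", "method"),
               sprintf("threshold file '%s'", path))
  marker_panel(thresholds = setNames(df$threshold, df$channel),
               methods = setNames(df$method, df$channel))
}
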
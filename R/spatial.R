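# Tumoral/stromal compartment assignment and per-core quantification.

#' Assign cells to the tumoral or stromal compartment
#'
#' A cell is tumoral iff its centroid lies inside or on the boundary of any
#' CK+ tumor polygon of its core's mask; otherwise it is stromal.
#'
#' @param cells Cells tibble with `x_um`, `y_um` (single core).
#' @param mask A `region_mask` for that core.
#' @return Character vector (`"tumoral"`/`"stromal"`), one per cell.
#' @export
assign_compartment <- function(cells, mask) {
  need_columns(cells, c("x_um", "y_um"), "cells table")
  assert_that(inherits(mask, "region_mask"), "mask must be a region_mask",
              "nkmihc_schema_error")
  inside <- points_in_mask(cells$x_um, cells$y_um, mask)
  ifelse(inside, "tumoral", "stromal")
}

#' Assign compartments across a cohort
#'
#' Cores without a mask are reported (warning naming the cores) and their
#' cells get `NA` compartments; other cores are unaffected.
#'
#' @param cells Cells tibble with `core_id`, `x_um`, `y_um`.
#' @param masks Named list of `region_mask` objects keyed by core id.
#' @return `cells` with a `compartment` column appended.
#' @export
assign_compartments <- function(cells, masks) {
  need_columns(cells, c("core_id", "x_um", "y_um"), "cells table")
  missing <- setdiff(unique(cells$core_id), names(masks))
  if (length(missing) > 0) {
    warn(sprintf("no mask for core(s): %s; their cells get NA compartments",
                 paste(missing, collapse = ", ")),
         class = "nkmihc_missing_mask")
  }
  comp <- rep(NA_character_, nrow(cells))
  for (cid in intersect(unique(cells$core_id), names(masks))) {
    sel <- cells$core_id == cid
    comp[sel] <- assign_compartment(cells[sel, ], masks[[cid]])
  }
  dplyr::mutate(cells, compartment = comp)
}

# Immune subsets tallied per core. Each entry is a predicate over the gated
# cell table.
subset_definitions <- function() {
  imm <- function(g, ph) g$phenotype == ph
  list(
    T_cell       = function(g) imm(g, "T_cell"),
    B_cell       = function(g) imm(g, "B_cell"),
    NK_cell      = function(g) imm(g, "NK_cell"),
    macrophage   = function(g) imm(g, "macrophage"),
    other_immune = function(g) imm(g, "other_immune"),
    CD57_T_cell  = function(g) imm(g, "T_cell") & g$cd57,
    CD57_NK_cell = function(g) imm(g, "NK_cell") & g$cd57,
    CD45_CD57    = function(g) g$phenotype %in% immune_phenotypes() & g$cd57,
    CD16_T_cell      = function(g) imm(g, "T_cell") & g$cd16,
    NKG2A_T_cell     = function(g) imm(g, "T_cell") & g$nkg2a,
    CD16_B_cell      = function(g) imm(g, "B_cell") & g$cd16,
    NKG2A_B_cell     = function(g) imm(g, "B_cell") & g$nkg2a,
    CD16_NK_cell     = function(g) imm(g, "NK_cell") & g$cd16,
    NKG2A_NK_cell    = function(g) imm(g, "NK_cell") & g$nkg2a,
    CD16_macrophage  = function(g) imm(g, "macrophage") & g$cd16,
    NKG2A_macrophage = function(g) imm(g, "macrophage") & g$nkg2a,
    HLAE_tumor   = function(g) g$phenotype == "tumor_cell" & g$pos_HLAE
  )
}

#' Quantify one core: counts, densities and composition
#'
#' Counts every immune subset (phenotypes, CD57+/receptor subsets, HLA-E+
#' tumor cells) in the tumoral, stromal and total compartments; densities in
#' cells/mm2 divide tumoral counts by the tumor area, stromal counts by the
#' stromal area and totals by the whole core area. Composition fractions are
#' computed among CD45+ cells and among CD45+CD57+ cells; fractions with a
#' zero denominator are reported as `NA`, never 0.
#'
#' @param calls Gated cells of one core ([gate_cells()] output) with a
#'   `compartment` column.
#' @param mask The core's `region_mask`.
#' @return A `core_quant` object: list with `core_id`, `quant` (long tibble
#'   `variable, compartment, count, area_mm2, density_per_mm2`) and
#'   `composition` (tibble `denominator, variable, fraction`).
#' @export
quantify_core <- function(calls, mask) {
  need_columns(calls, c("phenotype", "cd57", "cd16", "nkg2a", "pos_HLAE",
                        "compartment"), "gated cells table")
  areas <- c(tumoral = mask$tumor_area_mm2, stromal = mask$stromal_area_mm2,
             total = mask$core_area_mm2)
  defs <- subset_definitions()
  member <- do.call(cbind, lapply(defs, function(f) f(calls)))
  if (!is.matrix(member)) {
    member <- matrix(logical(0), 0, length(defs),
                     dimnames = list(NULL, names(defs)))
  }
  tum <- !is.na(calls$compartment) & calls$compartment == "tumoral"
  str_ <- !is.na(calls$compartment) & calls$compartment == "stromal"
  counts <- rbind(tumoral = colSums(member & tum),
                  stromal = colSums(member & str_),
                  total = colSums(member))
  for (comp in rownames(counts)) {
    if (areas[[comp]] <= 0 && any(counts[comp, ] > 0)) {
      bad <- names(which(counts[comp, ] > 0))[1]
      abort(sprintf("core %s: %s compartment has zero area but %d %s cell(s)",
                    mask$core_id, comp, counts[comp, bad], bad),
            class = c("nkmihc_geometry_error", "nkmihc_error"))
    }
  }
  quant <- tibble::tibble(
    variable = rep(names(defs), each = 3),
    compartment = rep(c("tumoral", "stromal", "total"), length(defs)),
    count = as.vector(counts[c("tumoral", "stromal", "total"),
                             names(defs)]),
    area_mm2 = rep(unname(areas[c("tumoral", "stromal", "total")]),
                   length(defs))
  )
  quant$density_per_mm2 <- ifelse(quant$area_mm2 > 0,
                                  quant$count / quant$area_mm2, NA_real_)

  total_count <- function(v) quant$count[quant$variable == v &
                                           quant$compartment == "total"]
  cd45_total <- sum(calls$phenotype %in% immune_phenotypes())
  comp_cd45 <- tibble::tibble(
    denominator = "CD45+",
    variable = immune_phenotypes(),
    fraction = if (cd45_total > 0) {
      vapply(immune_phenotypes(), total_count, numeric(1)) / cd45_total
    } else rep(NA_real_, length(immune_phenotypes()))
  )
  cd57_total <- total_count("CD45_CD57")
  comp_cd57 <- tibble::tibble(
    denominator = "CD45+CD57+",
    variable = c("CD57_T_cell", "CD57_NK_cell"),
    fraction = if (cd57_total > 0) {
      c(total_count("CD57_T_cell"), total_count("CD57_NK_cell")) / cd57_total
    } else c(NA_real_, NA_real_)
  )

  structure(
    list(core_id = mask$core_id, quant = quant,
         composition = dplyr::bind_rows(comp_cd45, comp_cd57)),
    class = "core_quant"
  )
}

#' @export
print.core_quant <- function(x, ...) {
  cat(sprintf("<core_quant %s: %d subset x compartment rows>\n",
              x$core_id, nrow(x$quant)))
  invisible(x)
}

#' Quantify every core of a gated cohort
#'
#' @param gated Gated cells tibble with `core_id` and `compartment`.
#' @param masks Named list of `region_mask` objects.
#' @return Named list of `core_quant` objects.
#' @export
quantify_cohort <- function(gated, masks) {
  need_columns(gated, "core_id", "gated cells table")
  core_ids <- unique(gated$core_id)
  missing <- setdiff(core_ids, names(masks))
  assert_that(length(missing) == 0,
              sprintf("no mask for core(s): %s", paste(missing, collapse = ", ")),
              "nkmihc_missing_mask")
  out <- lapply(core_ids, function(cid)
    quantify_core(gated[gated$core_id == cid, ], masks[[cid]]))
  setNames(out, core_ids)
}

#' Build the per-patient analysis table
#'
#' Joins per-core densities (wide: `<subset>_<compartment>` in cells/mm2)
#' and CD45+/CD57+ composition fractions onto the clinical table. The
#' core-to-patient mapping must be 1:1; unmatched cores or patients raise an
#' error listing the identifiers — rows are never dropped silently.
#'
#' @param core_quants Named list from [quantify_cohort()].
#' @param clinical Clinical tibble with `patient_id` and `core_id`.
#' @return One-row-per-patient tibble: clinical fields, MSI/molecular
#'   subtype, densities and composition fractions.
#' @export
cohort_table <- function(core_quants, clinical) {
  need_columns(clinical, c("patient_id", "core_id"), "clinical table")
  qids <- vapply(core_quants, `[[`, character(1), "core_id")
  only_q <- setdiff(qids, clinical$core_id)
  only_c <- setdiff(clinical$core_id, qids)
  if (length(only_q) > 0 || length(only_c) > 0) {
    abort(sprintf(
      "core/patient mismatch: cores without clinical row [%s]; clinical rows without core [%s]",
      paste(only_q, collapse = ", "), paste(only_c, collapse = ", ")),
      class = c("nkmihc_join_error", "nkmihc_error"))
  }
  assert_that(!any(duplicated(clinical$core_id)) && !any(duplicated(qids)),
              "core-to-patient mapping must be 1:1", "nkmihc_join_error")

  if (length(core_quants) == 0) {
    out <- classify_clinical(clinical)
    dens_names <- as.vector(outer(names(subset_definitions()),
                                  c("tumoral", "stromal", "total"), paste,
                                  sep = "_"))
    comp_names <- c(paste0("frac_", immune_phenotypes(), "_of_CD45"),
                    paste0("frac_", c("CD57_T_cell", "CD57_NK_cell"),
                           "_of_CD45CD57"))
    for (nm in c(dens_names, comp_names)) out[[nm]] <- numeric(0)
    return(tibble::as_tibble(out))
  }

  dens_wide <- dplyr::bind_rows(lapply(core_quants, function(q)
    dplyr::mutate(q$quant, core_id = q$core_id))) |>
    dplyr::mutate(name = paste(.data$variable, .data$compartment, sep = "_")) |>
    dplyr::select("core_id", "name", "density_per_mm2") |>
    tidyr::pivot_wider(names_from = "name", values_from = "density_per_mm2")
  comp_wide <- dplyr::bind_rows(lapply(core_quants, function(q)
    dplyr::mutate(q$composition, core_id = q$core_id))) |>
    dplyr::mutate(name = paste0("frac_", .data$variable, "_of_",
                                ifelse(.data$denominator == "CD45+",
                                       "CD45", "CD45CD57"))) |>
    dplyr::select("core_id", "name", "fraction") |>
    tidyr::pivot_wider(names_from = "name", values_from = "fraction")

  classify_clinical(clinical) |>
    dplyr::left_join(dens_wide, by = "core_id") |>
    dplyr::left_join(comp_wide, by = "core_id")
}

#' Derive a tumor mask from CK+ cell positions
#'
#' Helper for inputs lacking region geometry: the tumor region is taken as
#' the union of disks of radius `radius_um` around CK+ cells (each disk a
#' 16-gon). The tumor area is measured on a deterministic grid over the core
#' so overlapping disks are not double counted.
#'
#' @param cells Cells tibble of one core with `x_um`, `y_um` and a logical
#'   `ck_positive` column (or CK intensities plus `ck_threshold`).
#' @param core_id Core identifier.
#' @param core_diameter_um Core diameter in micrometres.
#' @param radius_um Disk radius around each CK+ cell (default 10).
#' @param ck_threshold Used to compute `CK > ck_threshold` when
#'   `ck_positive` is absent.
#' @param grid_n Grid resolution per axis for the area estimate.
#' @return A `region_mask`.
#' @export
mask_from_ck_cells <- function(cells, core_id, core_diameter_um,
                               radius_um = 10, ck_threshold = NULL,
                               grid_n = 250) {
  ckpos <- if ("ck_positive" %in% names(cells)) {
    cells$ck_positive
  } else {
    need_columns(cells, "CK", "cells table")
    assert_that(!is.null(ck_threshold),
                "supply ck_positive or a ck_threshold", "nkmihc_config_error")
    cells$CK > ck_threshold
  }
  cx <- cells$x_um[ckpos]; cy <- cells$y_um[ckpos]
  ang <- 2 * pi * (0:15) / 16
  polys <- lapply(seq_along(cx), function(i)
    cbind(cx[i] + radius_um * cos(ang), cy[i] + radius_um * sin(ang)))
  m <- new_region_mask(core_id, polys, core_diameter_um)
  # replace the naive summed polygon area by a grid union estimate
  r <- core_diameter_um / 2
  gx <- seq(0, core_diameter_um, length.out = grid_n)
  gr <- expand.grid(x = gx, y = gx)
  in_core <- (gr$x - r)^2 + (gr$y - r)^2 <= r^2
  covered <- rep(FALSE, nrow(gr))
  for (i in seq_along(cx)) {
    covered <- covered | ((gr$x - cx[i])^2 + (gr$y - cy[i])^2 <= radius_um^2)
  }
  frac <- if (any(in_core)) mean(covered[in_core]) else 0
  m$tumor_area_mm2 <- frac * m$core_area_mm2
  m$stromal_area_mm2 <- m$core_area_mm2 - m$tumor_area_mm2
  m
}
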
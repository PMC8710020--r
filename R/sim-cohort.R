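# Synthetic mIHC cohort generator: core geometry, cells, channel
# intensities, clinical covariates and proportional-hazards outcomes.

polygon_area <- function(poly) {
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

# Random convex polygon (convex hull of jittered ring points) centred at
# `center` with vertices within radius `max_r`.
random_convex_blob <- function(center, max_r, n_pts = 12) {
  ang <- sort(runif(n_pts, 0, 2 * pi))
  rad <- runif(n_pts, 0.5, 1) * max_r
  pts <- cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
  hull <- grDevices::chull(pts)
  pts[hull, , drop = FALSE]
}

scale_polygon <- function(poly, center, s) {
  cbind(center[1] + (poly[, 1] - center[1]) * s,
        center[2] + (poly[, 2] - center[2]) * s)
}

new_region_mask <- function(core_id, polygons, core_diameter_um) {
  r <- core_diameter_um / 2
  core_area <- pi * r^2 / UM2_PER_MM2
  tumor_area <- sum(vapply(polygons, polygon_area, numeric(1))) / UM2_PER_MM2
  structure(
    list(core_id = core_id, polygons = polygons,
         core_diameter_um = core_diameter_um,
         tumor_area_mm2 = tumor_area,
         stromal_area_mm2 = core_area - tumor_area,
         core_area_mm2 = core_area),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask %s: %d polygon(s), tumor %.3f / core %.3f mm2>\n",
              x$core_id, length(x$polygons), x$tumor_area_mm2,
              x$core_area_mm2))
  invisible(x)
}

# Tumor mask as a union of 1-5 disjoint random convex blobs, rescaled about
# their own centres so total area hits tumor_area_fraction exactly. Falls
# back to one near-circular 64-gon when the blob layout cannot reach the
# target fraction.
make_tumor_mask <- function(core_id, core_diameter_um, tumor_area_fraction) {
  r_core <- core_diameter_um / 2
  center_core <- c(r_core, r_core)  # origin at bounding-box corner
  target <- tumor_area_fraction * pi * r_core^2

  for (attempt in seq_len(20)) {
    k <- sample(1:5, 1)
    if (k == 1) {
      centers <- list(center_core)
      allowed <- 0.95 * r_core
    } else {
      ring <- 0.5 * r_core
      ang <- 2 * pi * (seq_len(k) - 1) / k + runif(1, 0, 2 * pi)
      centers <- lapply(ang, function(a) center_core + ring * c(cos(a), sin(a)))
      gap <- 2 * ring * sin(pi / k)          # distance between neighbours
      allowed <- 0.95 * min(gap / 2, r_core - ring)
    }
    blobs <- lapply(centers, random_convex_blob, max_r = allowed)
    total <- sum(vapply(blobs, polygon_area, numeric(1)))
    s <- sqrt(target / total)
    max_vr <- vapply(seq_along(blobs), function(i) {
      b <- blobs[[i]]; ctr <- centers[[i]]
      max(sqrt((b[, 1] - ctr[1])^2 + (b[, 2] - ctr[2])^2))
    }, numeric(1))
    if (all(s * max_vr <= allowed)) {
      polys <- lapply(seq_along(blobs), function(i)
        scale_polygon(blobs[[i]], centers[[i]], s))
      return(new_region_mask(core_id, polys, core_diameter_um))
    }
  }
  # near-circular fallback: regular 64-gon with exact target area
  n <- 64
  r <- sqrt(2 * target / (n * sin(2 * pi / n)))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  poly <- cbind(center_core[1] + r * cos(ang), center_core[2] + r * sin(ang))
  new_region_mask(core_id, list(poly), core_diameter_um)
}

points_in_mask <- function(x, y, mask) {
  inside <- rep(FALSE, length(x))
  for (poly in mask$polygons) {
    inside <- inside |
      pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
  }
  inside
}

#' Generate one synthetic TMA core
#'
#' Builds a CK+ tumor mask covering `tumor_area_fraction` of the core disc,
#' places cells uniformly over the disc, and draws truth phenotype, CD57 and
#' receptor statuses from the configured composition. CD45- cells inside the
#' mask are CK+ tumor cells; CD45- cells outside are CK- non-immune stroma,
#' so CK+ cells occur only inside the mask.
#'
#' @param config A [sim_config()].
#' @param core_id Core identifier (string).
#' @param core_index Integer index used to derive this core's random stream
#'   from the master seed.
#' @param n_cells Optional fixed cell count (default: Poisson around
#'   `cells_per_core_mean`).
#'
#' @return List with `mask` (a `region_mask`) and `cells` (tibble of truth
#'   labels and positions; no intensities yet).
#' @export
generate_core <- function(config, core_id, core_index = 1L, n_cells = NULL) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, core_index, 1L), {
    mask <- make_tumor_mask(core_id, config$core_diameter_um,
                            config$tumor_area_fraction)
    if (is.null(n_cells)) {
      n_cells <- stats::rpois(1, config$cells_per_core_mean)
    }
    r_core <- config$core_diameter_um / 2
    rad <- r_core * sqrt(runif(n_cells))
    ang <- runif(n_cells, 0, 2 * pi)
    x <- r_core + rad * cos(ang)
    y <- r_core + rad * sin(ang)
    inside <- points_in_mask(x, y, mask)

    classes <- names(config$composition)
    cls <- if (n_cells > 0) {
      sample(classes, n_cells, replace = TRUE, prob = config$composition)
    } else character(0)
    phen <- as.character(ifelse(cls == "CD45neg",
                                ifelse(inside, "tumor_cell",
                                       "other_nonimmune"), cls))

    cd57 <- phen == "NK_cell" |
      (phen == "T_cell" & runif(n_cells) < config$cd57_rate_T)
    cd16 <- nkg2a <- rep(FALSE, n_cells)
    for (ph in names(config$receptor_rates)) {
      sel <- phen == ph
      if (any(sel)) {
        rr <- config$receptor_rates[[ph]]
        cd16[sel] <- runif(sum(sel)) < rr[["CD16"]]
        nkg2a[sel] <- runif(sum(sel)) < rr[["NKG2A"]]
      }
    }
    hlae <- phen == "tumor_cell" & runif(n_cells) < config$hlae_model$base_rate

    cells <- tibble::tibble(
      cell_id = sprintf("%s_c%05d", core_id, seq_len(n_cells)),
      core_id = core_id,
      x_um = x, y_um = y,
      truth_phenotype = phen,
      truth_compartment = as.character(ifelse(inside, "tumoral", "stromal")),
      truth_cd57 = cd57, truth_cd16 = cd16, truth_nkg2a = nkg2a,
      truth_hlae = hlae
    )
    list(mask = mask, cells = cells)
  })
}

# Truth positivity per channel implied by phenotype + receptor truth.
truth_positivity <- function(cells) {
  ph <- cells$truth_phenotype
  immune <- ph %in% immune_phenotypes()
  tibble::tibble(
    CD45 = immune,
    CD3 = ph == "T_cell",
    CD20 = ph == "B_cell",
    CD57 = cells$truth_cd57,
    CD68 = ph == "macrophage",
    CK = ph == "tumor_cell",
    CD16 = cells$truth_cd16 & immune,
    NKG2A = cells$truth_nkg2a & immune,
    HLAE = cells$truth_hlae,
    SMA = ph == "other_nonimmune" & runif(nrow(cells)) < 0.6,
    KI67 = runif(nrow(cells)) < ifelse(ph == "tumor_cell", 0.2, 0.05)
  )
}

#' Simulate per-channel staining intensities
#'
#' Draws each cell's intensity for every panel channel from a two-component
#' log-normal mixture: the positive component if the cell is truth-positive
#' for that channel, otherwise the negative component. One random stream per
#' channel is derived from `seed`, so adding channels never perturbs others.
#'
#' @param cells Tibble of truth-labelled cells from [generate_core()].
#' @param intensity_model Per-channel component parameters (see
#'   [sim_config()]).
#' @param seed Integer seed for the channel streams.
#'
#' @return `cells` with one numeric intensity column per channel appended.
#' @export
simulate_intensities <- function(cells, intensity_model, seed = 1L) {
  for (ch in names(intensity_model)) {
    m <- intensity_model[[ch]]
    assert_that(m$pos_meanlog > m$neg_meanlog,
                sprintf("channel %s: positive component location must exceed the negative one", ch),
                "nkmihc_config_error")
  }
  pos <- with_seed(derive_seed(seed, 0L, 7L), truth_positivity(cells))
  out <- cells
  for (i in seq_along(intensity_model)) {
    ch <- names(intensity_model)[i]
    m <- intensity_model[[ch]]
    n <- nrow(cells)
    intens <- with_seed(derive_seed(seed, i, 2L), {
      meanlog <- ifelse(pos[[ch]], m$pos_meanlog, m$neg_meanlog)
      sdlog <- ifelse(pos[[ch]], m$pos_sdlog, m$neg_sdlog)
      exp(rnorm(n, meanlog, sdlog))
    })
    out[[ch]] <- pmax(intens, 0)
  }
  out
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times follow an exponential proportional-hazards model with hazard
#' `baseline * exp(sum(coef * covariate))`, independent exponential censoring
#' and administrative censoring at the follow-up horizon. Progression-free
#' survival is overall survival minus an exponential gap truncated at zero,
#' so PFS <= OS for every patient.
#'
#' @param covariates Data frame / matrix of per-patient covariates whose
#'   column names match `names(survival_model$coefficients)`; coefficients
#'   for unnamed columns default to 0.
#' @param survival_model See [sim_config()].
#' @param seed Integer seed.
#'
#' @return Tibble with `os_months`, `os_event`, `pfs_months`, `pfs_event`.
#' @export
simulate_survival <- function(covariates, survival_model, seed = 1L) {
  sm <- survival_model
  assert_that(sm$os_baseline_hazard > 0, "baseline hazard must be > 0",
              "nkmihc_config_error")
  assert_that(sm$censor_rate >= 0, "censoring rate must be >= 0",
              "nkmihc_config_error")
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  beta <- sm$coefficients
  lp <- rep(0, n)
  for (nm in names(beta)) {
    if (nm %in% names(covariates)) lp <- lp + beta[[nm]] * covariates[[nm]]
  }
  with_seed(seed, {
    hazard <- sm$os_baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    t_cens <- if (sm$censor_rate > 0) rexp(n, rate = sm$censor_rate) else rep(Inf, n)
    t_cens <- pmin(t_cens, sm$horizon_months)
    os_months <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    gap <- rexp(n, rate = 1 / max(sm$pfs_gap_mean, 1e-9))
    t_prog <- pmax(t_event - gap, 0.1)
    t_prog <- pmin(t_prog, t_event)          # guard when t_event < 0.1
    pfs_months <- pmin(t_prog, t_cens)
    pfs_event <- as.integer(t_prog <= t_cens)
    tibble::tibble(os_months, os_event, pfs_months, pfs_event)
  })
}

# Molecular subtype and consistent clinical flags per patient.
simulate_clinical_flags <- function(n, subtype_frequencies, seed) {
  with_seed(seed, {
    subtype <- sample(names(subtype_frequencies), n, replace = TRUE,
                      prob = subtype_frequencies)
    ebv <- as.integer(subtype == "EBV+")
    msi_names <- c("bat26", "bat25", "d5s346", "d17s250", "d2s123")
    flags <- matrix(0L, n, 5, dimnames = list(NULL, msi_names))
    for (i in seq_len(n)) {
      if (subtype[i] == "MSI-H") {
        k <- sample(2:5, 1)
        flags[i, sample(5, k)] <- 1L
      } else if (runif(1) < 0.1) {           # occasional MSI-L background
        flags[i, sample(5, 1)] <- 1L
      }
    }
    ecad <- as.integer(subtype == "EMT-like" |
                         (subtype %in% c("EBV+", "MSI-H") & runif(n) < 0.1))
    p53 <- as.integer(subtype == "non-EMT p53+" |
                        (subtype %in% c("EBV+", "MSI-H", "EMT-like") &
                           runif(n) < 0.3))
    stage <- sample(c("II", "III"), n, replace = TRUE, prob = c(14, 41) / 55)
    tibble::tibble(subtype_truth = subtype, ebv_ish = ebv,
                   tibble::as_tibble(flags), ecad_altered = ecad,
                   p53_positive = p53, stage = stage)
  })
}

#' Generate a full synthetic cohort bundle
#'
#' Runs [generate_core()] for every patient, links per-core HLA-E+ tumor-cell
#' rates to the z-scored truth tumoral immune densities, simulates channel
#' intensities, molecular/clinical flags and proportional-hazards outcomes
#' driven by the truth tumoral densities named in
#' `config$survival_model$coefficients`.
#'
#' @param config A [sim_config()].
#'
#' @return A `cohort_bundle`: list with `cells` (positions + intensities),
#'   `masks` (named list of `region_mask`), `clinical` (per-patient tibble),
#'   `truth` (generator-side labels, kept separate from pipeline inputs) and
#'   `config`.
#' @export
#' @examples
#' b <- simulate_cohort(sim_config(n_patients = 3, cells_per_core_mean = 150))
#' nrow(b$clinical)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  core_ids <- sprintf("core%03d", seq_len(n))
  patient_ids <- sprintf("P%03d", seq_len(n))

  cores <- lapply(seq_len(n), function(i)
    generate_core(config, core_ids[i], core_index = i))
  masks <- setNames(lapply(cores, `[[`, "mask"), core_ids)
  empty_cells <- generate_core(config, "core000", core_index = 0L,
                               n_cells = 0L)$cells
  cells <- dplyr::bind_rows(c(list(empty_cells[0, ]),
                              lapply(cores, `[[`, "cells")))

  # per-core truth densities (cells/mm2) of phenotypes of interest
  dens <- function(ph, comp = "tumoral") {
    vapply(seq_len(n), function(i) {
      cc <- cores[[i]]$cells
      k <- sum(cc$truth_phenotype == ph & cc$truth_compartment == comp)
      a <- if (comp == "tumoral") masks[[i]]$tumor_area_mm2
           else masks[[i]]$stromal_area_mm2
      if (a > 0) k / a else 0
    }, numeric(1))
  }
  zscore <- function(v) {
    s <- stats::sd(v)
    if (length(v) >= 2 && is.finite(s) && s > 0) (v - mean(v)) / s else v * 0
  }

  # HLA-E linkage: per-core positive-rate on the logit scale
  if (n > 0) {
    link <- config$hlae_model$link
    lp <- stats::qlogis(config$hlae_model$base_rate)
    lp <- rep(lp, n)
    for (ph in names(link)) lp <- lp + link[[ph]] * zscore(dens(ph))
    rate <- stats::plogis(lp)
    for (i in seq_len(n)) {
      cc <- cores[[i]]$cells
      tum <- cc$truth_phenotype == "tumor_cell"
      cc$truth_hlae <- with_seed(derive_seed(config$seed, i, 3L),
                                 tum & runif(nrow(cc)) < rate[i])
      cores[[i]]$cells <- cc
    }
    cells <- dplyr::bind_rows(lapply(cores, `[[`, "cells"))
  }

  empty_int <- simulate_intensities(empty_cells[0, ], config$intensity_model)
  cells_int <- dplyr::bind_rows(c(
    list(empty_int),
    lapply(seq_len(n), function(i)
      simulate_intensities(cores[[i]]$cells, config$intensity_model,
                           seed = derive_seed(config$seed, i, 4L)))
  ))

  covnames <- names(config$survival_model$coefficients)
  covs <- as.data.frame(setNames(lapply(covnames, function(nm) {
    # names like "NK_cell_tumoral": phenotype prefix + compartment suffix
    parts <- strsplit(nm, "_(?=[^_]+$)", perl = TRUE)[[1]]
    zscore(dens(parts[1], parts[2]))
  }), covnames))
  if (ncol(covs) == 0) covs <- data.frame(row.names = seq_len(n))

  surv <- simulate_survival(covs, config$survival_model,
                            seed = derive_seed(config$seed, 0L, 5L))
  flags <- simulate_clinical_flags(n, config$subtype_frequencies,
                                   seed = derive_seed(config$seed, 0L, 6L))

  clinical <- tibble::tibble(patient_id = patient_ids, core_id = core_ids)
  clinical <- dplyr::bind_cols(
    clinical,
    surv,
    flags[, c("stage", "ebv_ish", "bat26", "bat25", "d5s346", "d17s250",
              "d2s123", "ecad_altered", "p53_positive")]
  )

  truth <- dplyr::bind_cols(
    cells[, c("cell_id", "core_id")],
    cells[, grep("^truth_", names(cells), value = TRUE)]
  )
  truth_clinical <- tibble::tibble(patient_id = patient_ids,
                                   subtype_truth = flags$subtype_truth)

  structure(
    list(
      cells = cells_int[, c("cell_id", "core_id", "x_um", "y_um",
                            panel_channels())],
      masks = masks,
      clinical = clinical,
      truth = truth,
      truth_clinical = truth_clinical,
      config = config
    ),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle: %d patients, %d cells, %d masks>\n",
              nrow(x$clinical), nrow(x$cells), length(x$masks)))
  invisible(x)
}
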
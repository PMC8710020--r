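#' Configuration for the synthetic mIHC cohort generator
#'
#' Bundles every knob of the simulator: cohort size, core geometry, immune
#' composition, receptor co-expression rates, per-channel bimodal intensity
#' models, the HLA-E linkage model, the proportional-hazards survival model
#' and molecular-subtype frequencies. Defaults reproduce the statistical
#' structure of a 55-patient stage II-III gastric-cancer tissue microarray:
#' among CD45+ cells 65.5% T cells (23.2% of them CD57+), 5.3% B cells,
#' 3.8% CD57+ NK cells and 25.4% macrophages; receptor positivity 55.1%/27.9%
#' (CD16/NKG2A) on T cells and 59.3%/14.8% on NK cells.
#'
#' @param n_patients Number of patients (one TMA core each).
#' @param cells_per_core_mean Mean number of cells per core (Poisson).
#' @param core_diameter_um Core diameter in micrometres.
#' @param tumor_area_fraction Fraction of the core disc covered by the
#'   CK+ tumor mask, in (0, 1).
#' @param composition Named fractions over
#'   `c("T_cell","B_cell","NK_cell","macrophage","other_immune","CD45neg")`
#'   summing to 1. The first five are the split of all cells that are CD45+.
#' @param cd57_rate_T Fraction of T cells that are CD57+.
#' @param receptor_rates Named list per immune phenotype, each a named vector
#'   `c(CD16 = ..., NKG2A = ...)` of positivity rates.
#' @param intensity_model Named list per channel with elements
#'   `neg_meanlog, neg_sdlog, pos_meanlog, pos_sdlog` (log-normal components).
#' @param hlae_model List with `base_rate` (HLA-E+ fraction of tumor cells at
#'   average immune infiltration) and `link` (named log-odds coefficients per
#'   immune phenotype applied to the z-scored tumoral density of that
#'   phenotype).
#' @param survival_model List with `os_baseline_hazard` (events/month),
#'   `coefficients` (named log-hazard per covariate; covariates are z-scored
#'   truth densities, see [simulate_cohort()]), `censor_rate` (exponential
#'   censoring hazard), `horizon_months` (administrative censoring) and
#'   `pfs_gap_mean` (mean of the exponential OS-minus-PFS gap, months).
#' @param subtype_frequencies Named fractions over the five molecular
#'   subtypes `EBV+`, `MSI-H`, `EMT-like`, `non-EMT p53+`, `non-EMT p53-`.
#' @param seed Master integer seed; all per-core/per-channel streams are
#'   derived from it.
#'
#' @return A `sim_config` object (validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 4, cells_per_core_mean = 200)
#' cfg$composition
sim_config <- function(n_patients = 55,
                       cells_per_core_mean = 1500,
                       core_diameter_um = 1000,
                       tumor_area_fraction = 0.4,
                       composition = default_composition(),
                       cd57_rate_T = 0.232,
                       receptor_rates = default_receptor_rates(),
                       intensity_model = default_intensity_model(),
                       hlae_model = default_hlae_model(),
                       survival_model = default_survival_model(),
                       subtype_frequencies = default_subtype_frequencies(),
                       seed = 1L) {
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      cells_per_core_mean = as.numeric(cells_per_core_mean),
      core_diameter_um = as.numeric(core_diameter_um),
      tumor_area_fraction = as.numeric(tumor_area_fraction),
      composition = composition,
      cd57_rate_T = as.numeric(cd57_rate_T),
      receptor_rates = receptor_rates,
      intensity_model = intensity_model,
      hlae_model = hlae_model,
      survival_model = survival_model,
      subtype_frequencies = subtype_frequencies,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_composition <- function() {
  # 45% of all cells CD45+, split per the study's reported immune fractions.
  immune <- 0.45
  split <- c(T_cell = 0.655, B_cell = 0.053, NK_cell = 0.038,
             macrophage = 0.254, other_immune = 0)
  c(split * immune, CD45neg = 1 - immune)
}

#' @rdname sim_config
#' @export
default_receptor_rates <- function() {
  list(
    T_cell     = c(CD16 = 0.551, NKG2A = 0.279),
    B_cell     = c(CD16 = 0.05,  NKG2A = 0.02),
    NK_cell    = c(CD16 = 0.593, NKG2A = 0.148),
    macrophage = c(CD16 = 0.30,  NKG2A = 0.03),
    other_immune = c(CD16 = 0.05, NKG2A = 0.02)
  )
}

#' @rdname sim_config
#' @export
default_intensity_model <- function() {
  one <- list(neg_meanlog = 0, neg_sdlog = 0.35,
              pos_meanlog = log(12), pos_sdlog = 0.35)
  setNames(rep(list(one), length(panel_channels())), panel_channels())
}

#' @rdname sim_config
#' @export
default_hlae_model <- function() {
  list(base_rate = 0.35,
       link = c(T_cell = 0.6, B_cell = 0.3, macrophage = 0.4, NK_cell = 0))
}

#' @rdname sim_config
#' @export
default_survival_model <- function() {
  list(
    os_baseline_hazard = log(2) / 85.4,
    coefficients = c(NK_cell_tumoral = 0.5, T_cell_tumoral = -0.3),
    censor_rate = 0.006,
    horizon_months = 108,
    pfs_gap_mean = 20
  )
}

#' @rdname sim_config
#' @export
default_subtype_frequencies <- function() {
  c("EBV+" = 4, "MSI-H" = 7, "EMT-like" = 21,
    "non-EMT p53+" = 4, "non-EMT p53-" = 19) / 55
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_patients >= 0, "n_patients must be >= 0",
              "nkmihc_config_error")
  assert_that(cfg$tumor_area_fraction > 0 && cfg$tumor_area_fraction < 1,
              "tumor_area_fraction must lie strictly in (0, 1)",
              "nkmihc_config_error")
  comp <- cfg$composition
  expected <- c(immune_phenotypes(), "CD45neg")
  assert_that(all(expected %in% names(comp)),
              sprintf("composition must name fractions for: %s",
                      paste(expected, collapse = ", ")),
              "nkmihc_config_error")
  assert_that(all(comp >= 0 & comp <= 1),
              "composition fractions must lie in [0, 1]",
              "nkmihc_config_error")
  assert_that(abs(sum(comp) - 1) <= 1e-9,
              "composition fractions must sum to 1 (tolerance 1e-9)",
              "nkmihc_config_error")
  assert_that(cfg$cd57_rate_T >= 0 && cfg$cd57_rate_T <= 1,
              "cd57_rate_T must lie in [0, 1]", "nkmihc_config_error")
  for (ph in names(cfg$receptor_rates)) {
    r <- cfg$receptor_rates[[ph]]
    assert_that(all(r >= 0 & r <= 1),
                sprintf("receptor rates for %s must lie in [0, 1]", ph),
                "nkmihc_config_error")
  }
  for (ch in names(cfg$intensity_model)) {
    m <- cfg$intensity_model[[ch]]
    assert_that(m$pos_meanlog > m$neg_meanlog,
                sprintf("channel %s: positive component location must exceed the negative one", ch),
                "nkmihc_config_error")
    assert_that(m$neg_sdlog >= 0 && m$pos_sdlog >= 0,
                sprintf("channel %s: component scales must be >= 0", ch),
                "nkmihc_config_error")
  }
  sm <- cfg$survival_model
  assert_that(sm$os_baseline_hazard > 0,
              "baseline hazard must be > 0", "nkmihc_config_error")
  assert_that(sm$censor_rate >= 0 && sm$horizon_months >= 0,
              "censoring rate and horizon must be >= 0",
              "nkmihc_config_error")
  sf <- cfg$subtype_frequencies
  assert_that(abs(sum(sf) - 1) <= 1e-9 && all(sf >= 0),
              "subtype_frequencies must be non-negative and sum to 1",
              "nkmihc_config_error")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  patients: %d, cells/core ~ %g, core %g um, tumor fraction %g\n",
              x$n_patients, x$cells_per_core_mean, x$core_diameter_um,
              x$tumor_area_fraction))
  cat("  composition:",
      paste(sprintf("%s=%.3f", names(x$composition), x$composition),
            collapse = " "), "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
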
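# Reference in-silico experiment: end-to-end recovery of the cohort's
# immune composition through the full intensity -> threshold -> gate ->
# quantify path.

#' End-to-end immune-composition recovery experiment
#'
#' Generates a pooled synthetic cohort whose CD45+ cells follow the
#' configured immune composition (defaults: 65.5% T cells of which 23.2%
#' CD57+, 5.3% B cells, 3.8% CD57+ NK cells, 25.4% macrophages), simulates
#' bimodal channel intensities, derives every gating threshold from the
#' intensity distributions, gates hierarchically, and quantifies the
#' composition among gated CD45+ cells. CD45- cells (CK+ tumor inside the
#' mask, CK- stroma outside) are included so the CD45 and CK thresholds are
#' derivable from their own bimodal distributions.
#'
#' @param n_cd45 Target number of truth-CD45+ cells (>= 1e5 for the
#'   reference run; the realized count is binomial around this).
#' @param seed Master seed.
#' @param immune_fraction Fraction of all generated cells that are CD45+.
#' @return List with `composition` (tibble `variable, percent, n_denominator`
#'   covering the CD45+ phenotype split and the CD57+ NK share of
#'   CD45+CD57+ cells), the derived `panel`, and counts.
#' @export
composition_recovery_experiment <- function(n_cd45 = 1e5, seed = 1L,
                                            immune_fraction = 2 / 3) {
  split <- c(T_cell = 0.655, B_cell = 0.053, NK_cell = 0.038,
             macrophage = 0.254, other_immune = 0)
  comp <- c(split * immune_fraction, CD45neg = 1 - immune_fraction)
  cfg <- sim_config(
    n_patients = 1,
    composition = comp,
    cd57_rate_T = 0.232,
    seed = seed
  )
  n_cells <- round(n_cd45 / immune_fraction)
  core <- generate_core(cfg, "pooled", core_index = 1L, n_cells = n_cells)
  channels <- c("CD45", "CD3", "CD20", "CD57", "CD68", "CK", "CD16",
                "NKG2A", "HLAE")
  cells <- simulate_intensities(core$cells, cfg$intensity_model[channels],
                                seed = derive_seed(seed, 1L))
  panel <- derive_panel(cells, channels, seed = derive_seed(seed, 2L))
  gated <- gate_cells(cells, panel)
  gated$compartment <- assign_compartment(gated, core$mask)
  quant <- quantify_core(gated, core$mask)

  comp_tbl <- quant$composition
  cd45_n <- sum(gated$phenotype %in% immune_phenotypes())
  cd57_n <- quant$quant$count[quant$quant$variable == "CD45_CD57" &
                                quant$quant$compartment == "total"]
  frac <- function(v, denom) {
    comp_tbl$fraction[comp_tbl$variable == v & comp_tbl$denominator == denom]
  }
  composition <- tibble::tibble(
    variable = c("NK_cell", "T_cell", "macrophage", "B_cell",
                 "CD57_NK_of_CD57"),
    percent = 100 * c(frac("NK_cell", "CD45+"), frac("T_cell", "CD45+"),
                      frac("macrophage", "CD45+"), frac("B_cell", "CD45+"),
                      frac("CD57_NK_cell", "CD45+CD57+")),
    n_denominator = c(rep(cd45_n, 4), cd57_n)
  )
  list(composition = composition, panel = panel,
       n_cells = nrow(gated), n_cd45_gated = cd45_n, n_cd57_gated = cd57_n,
       truth_fractions = c(split[c("NK_cell", "T_cell", "macrophage",
                                   "B_cell")] * 100,
                           CD57_NK_of_CD57 = 100 * split[["NK_cell"]] /
                             (split[["NK_cell"]] +
                                0.232 * split[["T_cell"]])))
}
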
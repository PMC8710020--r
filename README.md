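# nkmihc

Quantification of the tumor immune microenvironment from segmented multiplex
immunohistochemistry (mIHC) cell tables, with an emphasis on CD57+ natural
killer (NK) cells and their activating/inhibitory receptors (CD16, NKG2A) in
gastric-cancer tissue microarrays.

## Who this is for

Pathology and tumor-immunology groups who have run an iterative mIHC panel
(CD57, NKG2A, CD16, HLA-E, CD3, CD20, CD45, CD68, CK, SMA, Ki-67), segmented
the images into per-cell intensity tables, and want a reproducible path from
those tables to per-patient immune statistics and survival associations —
without hand-tuned spreadsheets. Because cohorts of this kind are rarely
shareable, the package also ships a fully synthetic cohort generator with
the same statistical structure, so every stage is testable end to end.

## What it computes

1. **Marker thresholding** — per-channel positivity cut-offs derived from the
   intensity distribution: a two-component Gaussian mixture on
   log-intensity; the threshold is the intensity where the posterior
   probability of the positive component is 0.5. Manual cut-offs are a
   first-class alternative.
2. **Hierarchical gating** — an ordered lineage cascade on CD45+ cells:
   CD3+ → T cell; else CD20+ → B cell; else CD57+ → CD57+ NK cell; else
   CD68+ → macrophage; else other immune. CD45− cells are tumor (CK+) or
   non-immune stroma. CD16/NKG2A status is attached to every immune cell.
3. **Compartmentalization** — each cell is tumoral if its centroid lies in
   the CK+ tumor-region polygons of its core (boundary-inclusive), else
   stromal; densities are counts / compartment area in cells/mm².
4. **Association statistics** — Spearman rank correlations (mid-rank Pearson
   with a t-approximation p), Welch t comparisons across molecular/clinical
   strata, and OLS fits.
5. **Survival screen** — for every immune variable × compartment × endpoint
   (OS, PFS): a maximally selected rank-statistic cutpoint (the split
   maximizing the standardized log-rank statistic under a min-group
   constraint), then a univariate Cox proportional-hazards fit of high vs
   low, built from first principles (Newton–Raphson on the partial
   likelihood, Efron or Breslow ties):

   h(t | x) = h₀(t) · exp(β · 1[x > c*]),  c* = argmax_c |z_logrank(c)|

6. **Molecular classification** — MSI from the five Bethesda markers
   (≥2 unstable → MSI-H, 1 → MSI-L, 0 → MSS) and the five-subtype cascade
   EBV+ → MSI-H → EMT-like → non-EMT p53+ → non-EMT p53−.

## Worked example

```r
library(nkmihc)

# synthetic 55-patient cohort with the package's default composition
bundle <- simulate_cohort(sim_config(seed = 1))

# derive thresholds from the intensity distributions and gate
panel <- derive_panel(bundle$cells,
                      c("CD45", "CD3", "CD20", "CD57", "CD68",
                        "CK", "CD16", "NKG2A", "HLAE"))
gated <- gate_cells(bundle$cells, panel) |>
  assign_compartments(bundle$masks)

# per-core quantification and the per-patient analysis table
quants <- quantify_cohort(gated, bundle$masks)
analysis <- cohort_table(quants, bundle$clinical)

round(100 * colMeans(analysis[, c("frac_T_cell_of_CD45",
                                  "frac_B_cell_of_CD45",
                                  "frac_NK_cell_of_CD45",
                                  "frac_macrophage_of_CD45")]), 1)
#> frac_T_cell_of_CD45      frac_B_cell_of_CD45 
#>                65.6                      5.2 
#> frac_NK_cell_of_CD45 frac_macrophage_of_CD45 
#>                 3.8                     25.2

# survival screen: cutpoint + Cox HR per variable x compartment x endpoint
screen <- survival_screen(analysis)
dplyr::filter(screen, variable == "CD57_NK_cell", endpoint == "OS")
#> # A tibble: 3 x 12
#>   endpoint variable     compartment cutpoint n_low n_high    hr ci_low
#> 1 OS       CD57_NK_cell tumoral         41.4    43     12  2.33  0.890
#> 2 OS       CD57_NK_cell stromal         21.2     6     49  3.88  0.518
#> 3 OS       CD57_NK_cell total           40.7    49      6  2.54  0.848
```

Mean recovered composition matches the generator's configured fractions
(65.5% T, 5.3% B, 3.8% CD57+ NK, 25.4% macrophage among CD45+ cells), and
the screen reports the dichotomized hazard ratio with its Wald CI and
unadjusted p per combination. `autoplot()` methods draw KM curves, cutpoint
scans, correlation heatmaps and the forest plot of the screen; `tidy()` /
`glance()` tidy the fitted objects.

An end-to-end run with one config — including writing all stage CSVs and a
JSON manifest — is:

```r
run_pipeline(pipeline_config(out_dir = "out", simulate = sim_config(seed = 1)))
```

or, from a shell, the thin wrapper `inst/cli/nkmihc.R`
(`Rscript inst/cli/nkmihc.R run-all --out-dir out --seed 1`).

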
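---
title: "Models and methods behind nkmihc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nkmihc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkmihc)
```

nkmihc turns segmented multiplex-IHC (mIHC) cell tables from a
gastric-cancer tissue microarray (TMA) — one core per patient, eleven
stains per cell — into per-patient immune statistics and survival
associations, with particular attention to CD57+ NK cells and their CD16
(activating) and NKG2A (inhibitory) receptors. This vignette explains each
model, the tunable parameters, the numerical choices, and what the synthetic
cohort generator does and does not emulate.

## 1. Marker thresholding

A cell is called positive for a channel when its intensity exceeds the
channel's cut-off, **strictly**: ties at the threshold are negative. The
strict convention is arbitrary but must be fixed; it is applied uniformly
(positivity, and "high" groups in the survival screen).

`derive_threshold()` estimates a cut-off from the data: a two-component
Gaussian mixture with unequal variances is fitted to log intensities by EM
(via mclust, model `"V"`, `G = 2`), and the threshold is the intensity at
which the posterior probability of membership in the upper component is 0.5
— the decision boundary, located by `uniroot` between the two component
means (tolerance 1e-10). Log-normal components were chosen because stain
intensities are strictly positive and right-skewed.

Numerical details that matter:

* For more than 2,000 values the EM is initialised from a seed-controlled
  subsample of 2,000 (mclust's hierarchical initialisation is quadratic in
  the subsample size); the EM itself always runs on all values. Results are
  reproducible given the seed.
* The fit is rejected — a `threshold-underivable` error, so the caller can
  supply a manual cut-off — when the input has fewer than 50 finite values,
  zero variance, or no credible two-component structure (component
  separation below 2 pooled SDs, or a component weight below 1%). The last
  rule protects against the EM happily splitting a unimodal cloud in half,
  which would silently call ~50% of a single-population channel positive.
* Manual thresholds pass through unchanged. The pipeline accepts a mixture
  of per-channel methods, with manual values also serving as fallback when
  a distribution fit is underivable; both entry points are provided because
  practice mixes distribution-derived and visually chosen cut-offs, and a
  channel-by-channel attribution is generally not available.

## 2. Hierarchical gating

Phenotypes are assigned by an **ordered cascade** on the positivity calls,
not by exact profile matching:

| order | condition            | phenotype        |
|------:|----------------------|------------------|
| 1     | CD45+ CD3+            | T cell (CD57± recorded) |
| 2     | CD45+ CD20+           | B cell           |
| 3     | CD45+ CD57+           | CD57+ NK cell    |
| 4     | CD45+ CD68+           | macrophage       |
| 5     | CD45+ (none of above) | other immune     |
| 6     | CD45− CK+             | tumor cell       |
| 7     | CD45− CK−             | other non-immune |

The canonical immune profiles are mutually exclusive only when evaluated in
this order; biologically ambiguous double-positives (e.g. CD3+CD20+, or
CD57+CD68+ — NK by the cascade, macrophage by CD68) are resolved by cascade
order and flagged `multilineage` rather than dropped, so their prevalence
can be audited. CD16 and NKG2A statuses are copied onto every cell and are
non-exclusive (a CD16+NKG2A+ NK cell counts in both receptor subsets);
downstream tallies only count them on immune phenotypes. SMA and Ki-67 are
read and stored but play no gating role — the panel stains them, but no cell
class is defined by them here. HLA-E positivity on tumor cells uses exactly
the same thresholding machinery as the immune channels.

## 3. Compartments, densities, composition

Each cell is **tumoral** if its centroid lies inside or on the boundary of
any CK+ tumor polygon of its core, else **stromal** (point-in-polygon via
`pracma::inpolygon`, boundary-inclusive; the suite cross-checks it against a
hand-written even-odd ray-casting oracle). Centroid membership with an
inclusive boundary is the standard convention for segmented-cell tables;
the upstream rule being reproduced specifies no boundary handling.

Densities are counts divided by compartment area in mm² (1 mm² = 10⁶ µm²;
coordinates are µm in a per-core frame with origin at the bounding-box
corner). Three levels are reported per subset: tumoral (÷ tumor area),
stromal (÷ stromal area), and total (÷ whole-core area). The whole-core
denominator for the "total" level is a deliberate choice: it is the only
denominator under which the three levels are mutually consistent
(tumoral count + stromal count = total count, and tumor + stromal area =
core area). Composition fractions are computed among CD45+ cells and among
CD45+CD57+ cells; fractions with an empty denominator are reported as
missing, never as 0. Masks are taken as provided geometry; for inputs
without geometry, `mask_from_ck_cells()` derives one as the union of 10 µm
disks around CK+ cells, with the union area measured on a deterministic
grid so overlapping disks are not double-counted.

## 4. Association statistics

* **Spearman**: rho is the Pearson correlation of mid-ranks (average ranks
  on ties); p from the t-approximation with n−2 df, the common default at
  cohort scale (n ≈ 55). An exact permutation p is available for n ≤ 10,
  used to validate the approximation. rho = ±1 yields p below double
  precision; it is clamped to the smallest positive double so reported
  p-values always lie in (0, 1].
* **Welch t** (`stats::t.test`, unequal variances) for two-group
  comparisons; identical groups return t = 0, p = 1; a group with n < 2 or
  zero variance with unequal means is untestable.
* **OLS** (`stats::lm`) for simple linear fits; the slope test uses n−2 df.
* Densities enter tests untransformed (a log option would be easy to add,
  but the reference analysis reports tests on raw densities); **no
  multiplicity adjustment is applied anywhere** — the correlation heatmap
  and the survival screen flag unadjusted p < 0.05, and the inflation this
  causes in a cutpoint screen is measured instead (below).

## 5. Survival screen

All survival machinery is implemented from first principles and
cross-checked against the `survival` package in the test suite.

* **Kaplan–Meier**: product-limit estimator; S(0) = 1, right-continuous,
  non-increasing; median = first time with S(t) ≤ 0.5.
* **Log-rank**: observed-minus-expected events with hypergeometric variance
  accumulated over event times; chi-square with 1 df.
* **Maximally selected cutpoint**: every distinct observed covariate value
  c is a candidate provided both groups {x ≤ c} and {x > c} contain at
  least ⌈minprop·n⌉ subjects; the standardized log-rank statistic is
  evaluated at each and the c with the largest |z| wins, ties broken by the
  smallest c. `minprop` defaults to 0.1, the conventional default of the
  cutpoint-selection tooling this mirrors; it is exposed everywhere.
* **Cox**: univariate partial likelihood maximized by Newton–Raphson
  (covariate centred for numerical stability; steps damped to ±5; tolerance
  1e-9 on the step and 1e-7 on the score; max 50 iterations). Efron tie
  handling is the default — the default of the ecosystem this reproduces —
  with Breslow available for cross-checks; the two coincide exactly on
  tie-free data. SE from observed information; Wald CI and p. |β| exceeding
  15 is treated as monotone likelihood (perfect separation) and reported as
  an error with the direction of divergence. The score test at β = 0 is
  also computed; on a binary covariate with no ties it equals the log-rank
  chi-square, a classical identity the suite asserts to 1e-6.
* **Screen**: for each variable × compartment × endpoint (OS, PFS), the
  covariate is dichotomized at its maximally selected cutpoint
  (high = value **>** cutpoint, matching the strict positivity convention)
  and the Cox HR of high vs low is reported. High-vs-low was chosen as the
  primary mode because the screen's purpose is to reproduce a
  dichotomized forest display; `cox_univariate()` on the raw covariate
  provides the per-unit continuous alternative. Patients missing a
  covariate are dropped for that combination only; per-combination failures
  (constant covariate, separation) are recorded in the output and the
  screen continues.

Selecting the cutpoint that maximizes the log-rank statistic and then
testing at the same data inflates the false-positive rate well above the
nominal 5%; this screen applies no correction (by design, matching the
analysis it reproduces) and the null behaviour should be kept in mind when
reading the flags.

## 6. The synthetic cohort generator

Because cell-level mIHC cohorts of this kind are not publicly deposited,
`simulate_cohort()` generates one with the statistical structure the
analysis assumes. Defaults describe a 55-patient stage II–III gastric-cancer
TMA:

* **Composition** (among CD45+ cells): 65.5% T cells, 5.3% B cells, 3.8%
  CD57+ NK cells, 25.4% macrophages; 23.2% of T cells CD57+, which makes
  CD57+ NK cells 20% of CD45+CD57+ cells. CD45+ cells are 45% of all cells
  (a mid-range choice; only relative composition matters downstream).
* **Receptors**: CD16/NKG2A positivity 55.1%/27.9% on T cells and
  59.3%/14.8% on NK cells; B-cell and macrophage rates (5%/2% and 30%/3%)
  are plausibility choices, selected once so that T cells dominate the
  CD16+ and NKG2A+ pools with macrophages second.
* **Geometry**: one circular core per patient (default 1 mm diameter), a
  CK+ tumor mask built as the union of 1–5 disjoint random convex blobs
  rescaled to hit the target tumor-area fraction (default 0.4) exactly,
  with a near-circular 64-gon fallback when a blob layout cannot reach the
  target; cells placed uniformly over the disc. CD45− cells inside the mask
  are CK+ tumor cells, outside CK− stroma, so CK+ occurs only inside the
  mask.
* **Intensities**: per channel, two log-normal components (negative
  location log 1, positive log 12, both sdlog 0.35 — about 7 pooled SDs of
  separation, i.e. a clean bimodal histogram with per-channel
  misclassification ~2·10⁻⁴ at the mixture boundary).
* **HLA-E**: each core's HLA-E+ tumor-cell rate is linked on the logit
  scale to the z-scored truth tumoral densities of T cells, B cells and
  macrophages (coefficients 0.6/0.3/0.4) and not to NK density —
  reproducing the correlation structure the association stage is meant to
  detect.
* **Survival**: exponential proportional hazards. The OS baseline hazard
  log(2)/85.4 per month makes the median OS 85.4 months; the default
  log-hazard coefficients (+0.5 per SD of tumoral NK density, −0.3 per SD
  of tumoral T-cell density) encode the adverse-NK / protective-T structure
  of interest; independent exponential censoring (rate 0.006/month) plus a
  108-month administrative horizon yield roughly 40% observed deaths. PFS
  is OS minus an exponential gap (mean 20 months) truncated at zero and
  floored at 0.1 months, guaranteeing 0 < PFS ≤ OS without modelling
  disease states.
* **Clinical flags**: molecular subtype drawn from frequencies 4/7/21/4/19
  out of 55 (EBV+, MSI-H, EMT-like, non-EMT p53+, non-EMT p53−), then MSI
  marker flags, E-cadherin and p53 calls generated consistently with the
  subtype so the classifier recovers the truth label exactly; stage II:III
  at 14:41.
* **Reproducibility**: every per-core, per-channel draw uses its own stream
  derived from the master seed by a deterministic integer hash, so output
  is byte-identical under a fixed seed and independent of generation order.
* **Heterogeneity**: per-core composition is homogeneous by default
  (between-case variability in composition then arises only from sampling);
  beta-distributed per-core compositions were considered and left out of
  this version — the downstream statistics do not require them, and a
  heterogeneity knob without a calibration target invites overinterpretation.

Truth labels (phenotype, receptor status, compartment, HLA-E) are written to
a separate file that no pipeline stage reads, so recovery tests cannot leak.

**What passing tests show — and don't.** The generator emulates composition,
bimodal intensities, receptor co-expression, compartment geometry and
proportional-hazards outcomes. It does **not** emulate segmentation errors,
stain spillover or unmixing artifacts, spatial clustering of immune cells
(placement is uniform), multi-core-per-patient designs, or non-proportional
hazards. Recovery results on synthetic data therefore validate the
*computational* path — thresholds, gating, geometry, statistics — not the
biological fidelity of any particular antibody panel.

## 7. Problem sizes used in validation

The reference composition-recovery run (`scripts/acceptance.R` and the
acceptance suite) pools ~100,000 CD45+ cells plus half as many CD45− cells,
a size at which three binomial standard errors on the rarest class (3.8%)
are under 0.2 percentage points. Cutpoint-search equivalence is checked
exhaustively against a brute-force scan on 50 random datasets of n = 60;
Cox recovery uses n = 2,000 (point estimate) and 200 replicates of n = 500
(CI coverage); screen directionality uses 50 replicate cohorts of 55
patients at ~400 cells/core — cores there are down-sampled relative to real
TMA cores (thousands of cells) because composition, not count, drives every
statistic downstream of quantification; null calibration of Welch t and
log-rank uses 1,000 replicates each.

## 8. Known limitations

* The mixture threshold assumes a two-population channel; channels that are
  truly unimodal in a given cohort need a manual cut-off (the error message
  says so).
* No correction of cutpoint p-values for maximal selection; flags are
  exploratory.
* Single core per patient; no aggregation rules for multi-core designs.
* Uniform cell placement in the generator means spatial statistics beyond
  compartment membership cannot be validated against it.
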
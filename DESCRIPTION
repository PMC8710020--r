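Package: nkmihc
Title: NK-Cell-Focused Quantification of the Tumor Immune Microenvironment
    from Multiplex Immunohistochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying the tumor immune microenvironment
    from segmented multiplex immunohistochemistry (mIHC) cell tables, with
    emphasis on CD57+ natural killer (NK) cells and their CD16/NKG2A
    receptor subsets in gastric cancer tissue microarrays. Provides
    intensity-distribution marker thresholding, hierarchical lineage
    gating (CD45/CD3/CD20/CD57/CD68/CK), tumoral versus stromal
    compartment assignment against cytokeratin-positive region masks,
    per-core density and composition quantification, Spearman/Welch/OLS
    association statistics, and a survival screen built from first
    principles (Kaplan-Meier, log-rank, maximally selected rank-statistic
    cutpoints, univariate Cox proportional hazards with Efron or Breslow
    ties). A fully synthetic cohort generator with proportional-hazards
    outcomes makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    mclust,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
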
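test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(tumor_area_fraction = 1.2), class = "nkmihc_config_error")
  expect_error(sim_config(tumor_area_fraction = 0), class = "nkmihc_config_error")
  bad_comp <- default_composition()
  bad_comp["T_cell"] <- bad_comp["T_cell"] + 0.01
  expect_error(sim_config(composition = bad_comp), class = "nkmihc_config_error")
  im <- default_intensity_model()
  im$CD3$pos_meanlog <- im$CD3$neg_meanlog - 1
  expect_error(sim_config(intensity_model = im), class = "nkmihc_config_error")
  sm <- default_survival_model(); sm$os_baseline_hazard <- -1
  expect_error(sim_config(survival_model = sm), class = "nkmihc_config_error")
})

test_that("tumor mask area hits the target fraction and areas conserve", {
  for (f in c(0.15, 0.4, 0.7)) {
    cfg <- sim_config(tumor_area_fraction = f, seed = 3)
    core <- generate_core(cfg, "c1", core_index = 7L, n_cells = 10)
    m <- core$mask
    expect_lt(abs(m$tumor_area_mm2 / m$core_area_mm2 - f), 0.02 * f + 1e-9)
    expect_lt(abs(m$tumor_area_mm2 + m$stromal_area_mm2 - m$core_area_mm2),
              1e-6)
  }
})

test_that("cells are placed uniformly: mask occupancy matches area fraction", {
  cfg <- sim_config(tumor_area_fraction = 0.5, seed = 5)
  core <- generate_core(cfg, "c1", core_index = 1L, n_cells = 10000)
  frac_inside <- mean(core$cells$truth_compartment == "tumoral")
  # 3 binomial SE around 0.5 at n = 10,000
  expect_lt(abs(frac_inside - 0.5), 3 * sqrt(0.25 / 10000) + 0.02 * 0.5)
})

test_that("zero NK composition yields zero truth-NK cells", {
  comp <- default_composition()
  comp["T_cell"] <- comp["T_cell"] + comp["NK_cell"]
  comp["NK_cell"] <- 0
  core <- generate_core(sim_config(composition = comp), "c1", n_cells = 5000)
  expect_equal(sum(core$cells$truth_phenotype == "NK_cell"), 0)
})

test_that("CK+ tumor cells occur only inside the mask", {
  core <- generate_core(sim_config(seed = 9), "c1", n_cells = 5000)
  tum <- core$cells$truth_phenotype == "tumor_cell"
  expect_true(all(core$cells$truth_compartment[tum] == "tumoral"))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 3, cells_per_core_mean = 200, seed = 11)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$cells, b2$cells)
  expect_identical(b1$clinical, b2$clinical)
  b3 <- simulate_cohort(sim_config(n_patients = 3, cells_per_core_mean = 200,
                                   seed = 12))
  expect_false(identical(b1$cells, b3$cells))
})

test_that("truth composition is recovered over >= 1e5 CD45+ cells", {
  cfg <- sim_config(seed = 21)
  core <- generate_core(cfg, "big", n_cells = 230000)
  ph <- core$cells$truth_phenotype
  cd45 <- ph %in% c("T_cell", "B_cell", "NK_cell", "macrophage",
                    "other_immune")
  n <- sum(cd45)
  expect_gte(n, 1e5)
  comp <- cfg$composition[c("T_cell", "B_cell", "NK_cell", "macrophage")]
  target <- comp / sum(cfg$composition[c("T_cell", "B_cell", "NK_cell",
                                         "macrophage", "other_immune")])
  for (p in names(target)) {
    obs <- mean(ph[cd45] == p)
    se <- sqrt(target[[p]] * (1 - target[[p]]) / n)
    expect_lt(abs(obs - target[[p]]), 3 * se)
  }
})

test_that("intensities follow the truth component and clamp at zero", {
  cells <- generate_core(sim_config(seed = 2), "c1", n_cells = 2000)$cells
  model <- list(CD3 = list(neg_meanlog = 0, neg_sdlog = 0.1,
                           pos_meanlog = log(10), pos_sdlog = 0.1))
  out <- simulate_intensities(cells, model, seed = 4)
  tcell <- cells$truth_phenotype == "T_cell"
  expect_true(all(out$CD3 >= 0))
  # truth-negative cells stay near the negative location (1.0)
  expect_true(all(out$CD3[!tcell] < 3))
  expect_true(all(out$CD3[tcell] > 3))
})

test_that("zero-variance components give intensities exactly at the locations", {
  cells <- generate_core(sim_config(seed = 2), "c1", n_cells = 500)$cells
  model <- list(CD3 = list(neg_meanlog = 0, neg_sdlog = 0,
                           pos_meanlog = log(5), pos_sdlog = 0))
  out <- simulate_intensities(cells, model, seed = 1)
  expect_equal(sort(unique(round(out$CD3, 9))), c(1, 5))
})

test_that("overlapping mixture components are rejected", {
  cells <- generate_core(sim_config(seed = 2), "c1", n_cells = 100)$cells
  model <- list(CD3 = list(neg_meanlog = 1, neg_sdlog = 0.3,
                           pos_meanlog = 0.5, pos_sdlog = 0.3))
  expect_error(simulate_intensities(cells, model), class = "nkmihc_config_error")
})

test_that("simulated channel histograms are bimodal with a valley between components", {
  cells <- generate_core(sim_config(seed = 6), "c1", n_cells = 10000)$cells
  out <- simulate_intensities(cells, default_intensity_model(), seed = 6)
  lx <- log(out$CD45)
  h <- hist(lx, breaks = 40, plot = FALSE)
  m1 <- 0; m2 <- log(12)      # component locations on the log scale
  between <- h$mids > m1 + 0.2 & h$mids < m2 - 0.2
  at_modes <- min(max(h$counts[abs(h$mids - m1) < 0.3]),
                  max(h$counts[abs(h$mids - m2) < 0.3]))
  expect_lt(min(h$counts[between]), at_modes / 2)
})

test_that("survival times respect PFS <= OS and the horizon", {
  covs <- data.frame(x = rnorm(500))
  sm <- default_survival_model()
  out <- simulate_survival(covs, sm, seed = 8)
  expect_true(all(out$pfs_months <= out$os_months + 1e-12))
  expect_true(all(out$os_months <= sm$horizon_months))
  expect_true(all(out$os_event %in% 0:1))
})

test_that("a zero follow-up horizon censors everything at time zero", {
  sm <- default_survival_model(); sm$horizon_months <- 0
  out <- simulate_survival(data.frame(x = rnorm(50)), sm, seed = 1)
  expect_true(all(out$os_months == 0))
  expect_true(all(out$os_event == 0))
})

test_that("negative baseline hazard is rejected", {
  sm <- default_survival_model(); sm$os_baseline_hazard <- -0.1
  expect_error(simulate_survival(data.frame(x = 1:5), sm),
               class = "nkmihc_config_error")
})

test_that("a log(2) binary effect is recovered as hazard ratio ~2 by a Cox oracle", {
  skip_if_not_installed("survival")
  sm <- default_survival_model()
  sm$coefficients <- c(grp = log(2))
  sm$censor_rate <- 0
  covs <- data.frame(grp = rep(0:1, each = 1000))
  out <- simulate_survival(covs, sm, seed = 13)
  fit <- survival::coxph(survival::Surv(pmax(out$os_months, 1e-6),
                                        out$os_event) ~ grp, data = covs)
  expect_lt(abs(exp(unname(coef(fit))) - 2), 0.25)
})

test_that("Cox confidence intervals cover the generating log-hazard", {
  # generator/estimator agreement: 95% Wald CIs at n = 500 cover beta in
  # >= 90% of 200 replicates for beta in {0, 0.5, 1}
  for (beta in c(0, 0.5, 1)) {
    sm <- default_survival_model()
    sm$coefficients <- c(grp = beta)
    sm$censor_rate <- 0.003
    cover <- vapply(seq_len(200), function(r) {
      covs <- data.frame(grp = rep(0:1, each = 250))
      out <- simulate_survival(covs, sm, seed = 5000 + 211 * r + round(97 * beta))
      ok <- out$os_months > 0
      fit <- cox_univariate(out$os_months[ok], out$os_event[ok], covs$grp[ok])
      beta >= log(fit$ci95[["low"]]) && beta <= log(fit$ci95[["high"]])
    }, logical(1))
    expect_gte(mean(cover), 0.9)
  }
})

test_that("fixtures round-trip losslessly and deterministically", {
  b <- small_bundle()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(b, d1)
  write_fixture(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  rt <- read_fixture(d1)
  expect_equal(as.data.frame(rt$cells), as.data.frame(b$cells),
               tolerance = 1e-12)
  expect_equal(as.data.frame(rt$clinical), as.data.frame(b$clinical),
               tolerance = 1e-12)
  expect_equal(as.data.frame(rt$truth), as.data.frame(b$truth))
  expect_equal(names(rt$masks), names(b$masks))
  m1 <- rt$masks[[1]]; m2 <- b$masks[[1]]
  expect_equal(m1$tumor_area_mm2, m2$tumor_area_mm2, tolerance = 1e-9)
  expect_equal(m1$polygons[[1]], m2$polygons[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rt$config$composition, b$config$composition)
})

test_that("an empty cohort writes valid files with headers", {
  b <- simulate_cohort(sim_config(n_patients = 0, seed = 1))
  d <- withr::local_tempdir()
  write_fixture(b, d)
  cells <- read_cells(file.path(d, "cells.csv"))
  expect_equal(nrow(cells), 0)
  expect_true(all(c("cell_id", "CD57", "NKG2A") %in% names(cells)))
  clin <- read_clinical(file.path(d, "clinical.csv"))
  expect_equal(nrow(clin), 0)
})

test_that("a 55-patient cohort yields 55 clinical rows and >= 55 mask features", {
  b <- simulate_cohort(sim_config(n_patients = 55, cells_per_core_mean = 60,
                                  seed = 31))
  expect_equal(nrow(b$clinical), 55)
  d <- withr::local_tempdir()
  write_fixture(b, d)
  fc <- jsonlite::read_json(file.path(d, "masks.geojson"))
  expect_gte(length(fc$features), 55)
  expect_equal(nrow(read_clinical(file.path(d, "clinical.csv"))), 55)
})

test_that("every cell has a mask and a clinical record (bundle invariant)", {
  b <- small_bundle()
  expect_true(all(b$cells$core_id %in% names(b$masks)))
  expect_true(all(b$cells$core_id %in% b$clinical$core_id))
  expect_setequal(b$truth$cell_id, b$cells$cell_id)
})
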
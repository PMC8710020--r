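# Independent oracles used across the suite.

# Even-odd ray casting, one point at a time (textbook form, kept deliberately
# naive and separate from the package's geometry path).
pip_raycast <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Hand-enumerated lineage truth table, written as explicit nested rules
# independent of the package's case_when cascade.
phenotype_oracle <- function(cd45, cd3, cd20, cd57, cd68, ck) {
  if (cd45) {
    if (cd3) return("T_cell")
    if (cd20) return("B_cell")
    if (cd57) return("NK_cell")
    if (cd68) return("macrophage")
    return("other_immune")
  }
  if (ck) return("tumor_cell")
  "other_nonimmune"
}

# Brute-force mid-rank Pearson (Spearman oracle).
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Small positivity tibble for cascade tests.
pos_tbl <- function(cd45, cd3 = FALSE, cd20 = FALSE, cd57 = FALSE,
                    cd68 = FALSE, ck = FALSE, cd16 = FALSE, nkg2a = FALSE) {
  tibble::tibble(cell_id = paste0("c", seq_along(cd45)),
                 CD45 = cd45, CD3 = cd3, CD20 = cd20, CD57 = cd57,
                 CD68 = cd68, CK = ck, CD16 = cd16, NKG2A = nkg2a)
}

gate_channel_set <- c("CD45", "CD3", "CD20", "CD57", "CD68", "CK",
                      "CD16", "NKG2A", "HLAE")

# One small cohort shared by several test files (built once per run).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(n_patients = 6,
                                           cells_per_core_mean = 500,
                                           seed = 42))
    }
    cache
  }
})
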
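#' @importFrom rlang abort warn .data :=
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats rnorm runif rexp rbinom pt qnorm pnorm pchisq setNames
#'   complete.cases
#' @importFrom utils head tail
NULL

# Deterministic integer hash used to split one master seed into independent
# per-(core, purpose) streams, so generation order never changes output.
# Values stay below 2^31 (R integer range).
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- (as.numeric(master) %% 2147483629) + 1
  for (k in idx) {
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483629
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

# FNV-1a over a string; used for config hashes in the run manifest.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

assert_that <- function(ok, msg, class = "nkmihc_error") {
  if (!isTRUE(ok)) abort(msg, class = c(class, "nkmihc_error"))
  invisible(TRUE)
}

need_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = c("nkmihc_schema_error", "nkmihc_error")
    )
  }
  invisible(TRUE)
}

UM2_PER_MM2 <- 1e6

#' Marker channels used throughout the pipeline
#'
#' The eleven-antibody mIHC panel: NK-associated markers (CD57, NKG2A, CD16,
#' HLA-E), lineage markers (CD3, CD20, CD45, CD68, CK) and the stromal /
#' proliferation stains (SMA, Ki-67) that are recorded but not gated.
#'
#' @return Character vector of channel names in canonical order.
#' @export
panel_channels <- function() {
  c("CD57", "NKG2A", "CD16", "HLAE", "CD3", "CD20", "CD45", "CD68",
    "CK", "SMA", "KI67")
}

# Channels actually consulted by the lineage gating cascade.
gating_channels <- function() c("CD45", "CD3", "CD20", "CD57", "CD68", "CK")

phenotype_levels <- function() {
  c("T_cell", "B_cell", "NK_cell", "macrophage", "other_immune",
    "tumor_cell", "other_nonimmune")
}

immune_phenotypes <- function() {
  c("T_cell", "B_cell", "NK_cell", "macrophage", "other_immune")
}
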
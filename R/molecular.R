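# Molecular classification rules: MSI from five PCR markers and the
# five-group molecular subtype cascade.

#' Classify microsatellite instability status
#'
#' Five marker instability flags (BAT-26, BAT-25, D5S346, D17S250, D2S123):
#' two or more unstable markers give MSI-H, exactly one gives MSI-L, none
#' gives MSS.
#'
#' @param flags Logical/0-1 vector of length 5, or a data frame with columns
#'   `bat26, bat25, d5s346, d17s250, d2s123` (one row per tumor).
#' @return Character vector of `"MSS"`, `"MSI-L"` or `"MSI-H"`.
#' @export
#' @examples
#' classify_msi(c(1, 1, 0, 0, 0))
classify_msi <- function(flags) {
  if (is.data.frame(flags)) {
    cols <- c("bat26", "bat25", "d5s346", "d17s250", "d2s123")
    need_columns(flags, cols, "MSI flag table")
    k <- rowSums(flags[, cols] != 0)
  } else {
    assert_that(length(flags) == 5,
                "classify_msi expects exactly 5 marker flags",
                "nkmihc_schema_error")
    k <- sum(flags != 0)
  }
  dplyr::case_when(k >= 2 ~ "MSI-H", k == 1 ~ "MSI-L", TRUE ~ "MSS")
}

#' Classify the molecular subtype of a gastric cancer
#'
#' Ordered rule over EBV ISH, MSI status and conventional IHC: EBV positive
#' gives EBV+; else MSI-H gives MSI-H; else altered E-cadherin gives
#' EMT-like; else p53 positive gives non-EMT p53+; else non-EMT p53-.
#'
#' @param ebv Logical/0-1: EBV ISH positive.
#' @param msi `"MSS"`, `"MSI-L"` or `"MSI-H"`.
#' @param ecad_altered Logical/0-1: E-cadherin loss or aberrant staining.
#' @param p53_positive Logical/0-1: strong nuclear p53 in > 10% of tumor
#'   cells.
#' @return Character vector over `"EBV+", "MSI-H", "EMT-like",
#'   "non-EMT p53+", "non-EMT p53-"`. Vectorised over its arguments.
#' @export
#' @examples
#' classify_molecular_subtype(FALSE, "MSS", TRUE, TRUE)
classify_molecular_subtype <- function(ebv, msi, ecad_altered, p53_positive) {
  assert_that(all(msi %in% c("MSS", "MSI-L", "MSI-H")),
              "msi must be one of MSS, MSI-L, MSI-H", "nkmihc_schema_error")
  dplyr::case_when(
    as.logical(ebv) ~ "EBV+",
    msi == "MSI-H" ~ "MSI-H",
    as.logical(ecad_altered) ~ "EMT-like",
    as.logical(p53_positive) ~ "non-EMT p53+",
    TRUE ~ "non-EMT p53-"
  )
}

#' Append MSI and molecular subtype to a clinical table
#'
#' @param clinical Clinical tibble with the five MSI flags, `ebv_ish`,
#'   `ecad_altered` and `p53_positive`.
#' @return `clinical` with `msi_status` and `molecular_subtype` appended.
#' @export
classify_clinical <- function(clinical) {
  msi <- classify_msi(clinical)
  dplyr::mutate(clinical,
                msi_status = msi,
                molecular_subtype = classify_molecular_subtype(
                  .data$ebv_ish, msi, .data$ecad_altered, .data$p53_positive))
}
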
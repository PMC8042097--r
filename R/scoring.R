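#' Z-score a gene's expression across a cohort and call high expressers
#'
#' Classifies cohort samples as high expressers of a single gene (the
#' TCGA-style SOX10-high call): `z = (x - mean) / sd` across the cohort and
#' a sample is `high` when `z > threshold_z` (strict). With the default
#' threshold of 1 a normally distributed cohort yields a high fraction of
#' about 16% — a "subset" of tumours on the order reported for SOX10.
#' Pre-computed z-scores (e.g. downloaded ones) are accepted via
#' `values_are_z`.
#'
#' @param cohort tibble with one row per sample.
#' @param value column holding the expression values (or z-scores).
#' @param threshold_z classification threshold on z (strict `>`).
#' @param values_are_z set `TRUE` when `value` already holds z-scores.
#' @return the input tibble with added columns `z` and `label`
#'   (`"high"`/`"not-high"`). Raising `threshold_z` never adds a high label.
#' @export
zscore_and_classify <- function(cohort, value, threshold_z = 1,
                                values_are_z = FALSE) {
  stopifnot(is.data.frame(cohort))
  v <- dplyr::pull(cohort, {{ value }})
  if (length(v) < 3) abort("need at least 3 samples")
  if (any(!is.finite(v))) abort("expression values must be finite")
  if (values_are_z) {
    z <- v
  } else {
    s <- sd(v)
    if (s == 0) abort("zero variance across the cohort; z-scores undefined")
    z <- (v - mean(v)) / s
  }
  dplyr::mutate(cohort, z = z,
                label = ifelse(z > threshold_z, "high", "not-high"))
}

#' qPCR relative expression by reference-gene normalisation
#'
#' The delta-Ct method: `2^-(ct_gene - ct_reference)`, i.e. expression of a
#' gene of interest relative to a housekeeping reference (GAPDH in the
#' assays this mirrors). Optionally a second normalisation (delta-delta-Ct)
#' against a calibrator sample's delta-Ct gives fold change over control.
#'
#' @param ct_gene,ct_reference cycle-threshold values (positive; vectorised).
#' @param calibrator_dct optional delta-Ct of the calibrator sample; when
#'   given, returns `2^-((ct_gene - ct_reference) - calibrator_dct)`.
#' @return relative expression values.
#' @export
qpcr_relative_expression <- function(ct_gene, ct_reference,
                                     calibrator_dct = NULL) {
  if (missing(ct_reference) || is.null(ct_reference)) {
    abort("a reference-gene Ct is required")
  }
  if (any(ct_gene <= 0) || any(ct_reference <= 0)) {
    abort("Ct values must be positive")
  }
  dct <- ct_gene - ct_reference
  if (!is.null(calibrator_dct)) dct <- dct - calibrator_dct
  2^(-dct)
}
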
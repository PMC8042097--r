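#' PCA of samples from a count matrix
#'
#' Counts are size-factor normalised, transformed with `log2(x + 1)` (a
#' light-weight stand-in for variance-stabilising transforms), restricted to
#' the `n_top_genes` most variable genes, and decomposed by SVD
#' (`prcomp`, centred, unscaled). Each PC's sign is fixed by forcing its
#' largest-magnitude gene loading positive, so results do not depend on the
#' SVD implementation's sign choices, and permuting sample order permutes
#' the output rows identically.
#'
#' @param counts filtered gene-by-sample count tibble (>= 2 samples).
#' @param n_top_genes number of most-variable genes used (default 500).
#' @param size_factors optional precomputed size-factor tibble.
#' @return a `wm_pca` tibble: `sample`, `condition`, `replicate`, `PC1`,
#'   `PC2`, ... with the per-PC variance fractions in the
#'   `"variance_explained"` attribute.
#' @export
pca_samples <- function(counts, n_top_genes = 500, size_factors = NULL) {
  m <- as_expr_matrix(counts)
  if (ncol(m) < 2) abort("PCA needs at least 2 samples")
  lg <- log2(normalised_counts(counts, size_factors) + 1)
  rv <- apply(lg, 1, var)
  top <- head(order(rv, decreasing = TRUE), n_top_genes)
  pc <- prcomp(t(lg[top, , drop = FALSE]), center = TRUE, scale. = FALSE)

  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }

  info <- parse_sample_labels(colnames(m))
  scores <- tibble::as_tibble(pc$x)
  out <- dplyr::bind_cols(info, scores)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(out,
            variance_explained = var_frac,
            class = c("wm_pca", class(out)))
}

#' @export
glance.wm_pca <- function(x, ...) {
  v <- attr(x, "variance_explained")
  tibble::tibble(
    n_samples = nrow(x),
    pc1_var = v[1],
    pc2_var = if (length(v) > 1) v[2] else NA_real_
  )
}
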
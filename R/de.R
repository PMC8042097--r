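#' Filter a count matrix by minimum counts in minimum samples
#'
#' Keeps a gene when at least `min_samples` samples have at least `min_count`
#' counts — the standard pre-filter applied before differential expression
#' (defaults: 5 counts in 3 samples). Idempotent; gene order preserved.
#'
#' @param counts gene-by-sample tibble of integer counts.
#' @param min_count,min_samples the filter thresholds.
#' @return the filtered tibble (possibly zero rows, with a message).
#' @export
filter_counts <- function(counts, min_count = 5, min_samples = 3) {
  m <- as_expr_matrix(counts)
  keep <- rowSums(m >= min_count) >= min_samples
  if (!any(keep)) inform("no gene passes the count filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants estimated as the median, over genes
#' with a positive geometric mean across samples, of the ratio of the
#' sample's count to that geometric mean — the estimator popularised by
#' DESeq. Relative to a fixed reference (`geo_means`), scaling one sample's
#' column by `c` scales only that sample's factor by `c`; with the default
#' in-matrix reference the same scaling also shifts the common reference by
#' `c^(1/m)`, so only factor ratios obey the law exactly.
#'
#' @param counts gene-by-sample tibble of counts.
#' @param geo_means optional per-gene reference geometric means (same order
#'   as `counts$gene`); default: computed from the matrix itself.
#' @return tibble with columns `sample` and `size_factor`.
#' @export
estimate_size_factors <- function(counts, geo_means = NULL) {
  m <- as_expr_matrix(counts)
  log_geo <- if (is.null(geo_means)) rowMeans(log(m)) else log(geo_means)
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    abort(paste(
      "no gene has nonzero counts in every sample;",
      "size factors need at least one such gene (filter or subset samples)"
    ))
  }
  sf <- apply(m[usable, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo[usable]))
  })
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

normalised_counts <- function(counts, size_factors = NULL) {
  m <- as_expr_matrix(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  if (anyNA(sf)) abort("size factors missing for some samples")
  sweep(m, 2, sf, "/")
}

#' Negative-binomial Wald test for differential expression
#'
#' Region-specific differential expression on filtered counts: counts are
#' normalised by median-of-ratios size factors, a per-gene NB dispersion is
#' estimated by method of moments (variance = mu + dispersion * mu^2, pooled
#' over the two groups and floored at `dispersion_floor`), and the log2
#' expression ratio of `condition_a` over `condition_b` (pseudo-count 0.5)
#' is tested with a Wald statistic. The statistic is referred to a
#' t distribution with `n_a + n_b - 2` degrees of freedom — the moment
#' estimator is noisy at typical replicate numbers and the t reference keeps
#' the null false-positive rate at its nominal level. P-values are
#' Benjamini-Hochberg adjusted across tested genes; genes with zero counts
#' in both groups get NA statistics and are excluded from the BH denominator.
#'
#' @param counts filtered gene-by-sample tibble (headers
#'   `condition:replicate`); >= 2 replicates per tested condition.
#' @param condition_a,condition_b numerator and denominator conditions of
#'   the comparison (e.g. `"CC"` vs `"Bulk"`).
#' @param size_factors optional precomputed tibble from
#'   [estimate_size_factors()] (useful to share factors across comparisons);
#'   default: estimated from the two tested conditions.
#' @param dispersion_floor lower bound on the moment dispersion estimate.
#' @return a `wm_de` tibble: `gene`, `base_mean`, `log2_ratio`, `lfc_se`,
#'   `stat`, `p`, `p_adj`, with the comparison stored as an attribute.
#' @export
test_differential_expression <- function(counts, condition_a, condition_b,
                                         size_factors = NULL,
                                         dispersion_floor = 1e-4) {
  m <- as_expr_matrix(counts)
  info <- parse_sample_labels(colnames(m))
  for (cond in c(condition_a, condition_b)) {
    if (sum(info$condition == cond) < 2) {
      abort(sprintf("condition '%s' needs >= 2 replicates", cond))
    }
  }
  keep_samples <- info$sample[info$condition %in% c(condition_a, condition_b)]
  sub <- counts[c("gene", keep_samples)]
  norm <- normalised_counts(sub, size_factors)
  info <- info[info$sample %in% keep_samples, ]

  a_cols <- info$sample[info$condition == condition_a]
  b_cols <- info$sample[info$condition == condition_b]
  na <- length(a_cols)
  nb <- length(b_cols)
  mu_a <- rowMeans(norm[, a_cols, drop = FALSE])
  mu_b <- rowMeans(norm[, b_cols, drop = FALSE])
  v_a <- apply(norm[, a_cols, drop = FALSE], 1, var)
  v_b <- apply(norm[, b_cols, drop = FALSE], 1, var)

  # pooled method-of-moments dispersion, floored
  disp_a <- (v_a - mu_a) / mu_a^2
  disp_b <- (v_b - mu_b) / mu_b^2
  disp <- pmax(dispersion_floor,
               rowMeans(cbind(disp_a, disp_b), na.rm = TRUE),
               na.rm = TRUE)

  log2_ratio <- log2((mu_a + 0.5) / (mu_b + 0.5))
  se_ln <- sqrt((1 / (mu_a + 0.5) + disp) / na +
                  (1 / (mu_b + 0.5) + disp) / nb)
  stat <- (log(mu_a + 0.5) - log(mu_b + 0.5)) / se_ln
  p <- 2 * pt(-abs(stat), df = na + nb - 2)

  empty <- mu_a == 0 & mu_b == 0
  log2_ratio[empty] <- NA_real_
  stat[empty] <- NA_real_
  p[empty] <- NA_real_

  res <- tibble::tibble(
    gene = rownames(norm),
    base_mean = rowMeans(norm),
    log2_ratio = log2_ratio,
    lfc_se = se_ln / log(2),
    stat = stat,
    p = p,
    p_adj = p.adjust(p, method = "BH")
  )
  structure(res,
            comparison = c(condition_a, condition_b),
            class = c("wm_de", class(res)))
}

#' @export
glance.wm_de <- function(x, alpha = 0.05, lfc_min = 0.58, ...) {
  tibble::tibble(
    comparison = paste(attr(x, "comparison"), collapse = " vs "),
    n_tested = sum(!is.na(x$p)),
    n_significant = sum(x$p_adj < alpha, na.rm = TRUE),
    n_regulated = sum(x$p_adj < alpha & abs(x$log2_ratio) > lfc_min,
                      na.rm = TRUE)
  )
}

#' @export
tidy.wm_de <- function(x, ...) {
  tibble::as_tibble(x)
}
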
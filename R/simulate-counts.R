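#' Simulate region-specific RNA-seq count matrices with planted effects
#'
#' Draws integer negative-binomial counts for tumour-bulk (`Bulk`) and the
#' two invaded regions (`CC`, corpus callosum white matter; `ST`, striatal
#' grey matter), with differential expression planted as log2 fold changes of
#' chosen genes in chosen regions relative to Bulk. The NB model is the usual
#' mean-dispersion form, variance = mu + dispersion * mu^2.
#'
#' @param genes character vector of gene ids, or a single count (gene ids are
#'   then generated).
#' @param n_per_region replicates per region; a single number or a named
#'   vector over `Bulk`, `CC`, `ST`. At least 2 each.
#' @param de tibble of planted effects with columns `gene`, `region`
#'   (`"CC"` or `"ST"`), `log2fc`; `NULL` for a null dataset. The expected
#'   fold change of a planted gene in its region relative to Bulk is
#'   `2^log2fc`.
#' @param dispersion NB dispersion, recycled per gene (> 0). Default 0.1.
#' @param size_factors per-sample positive scalars (recycled), applied
#'   multiplicatively to the expected counts.
#' @param baseline_log_mean,baseline_log_sd natural-log-normal distribution
#'   of per-gene baseline mean counts (defaults give a median of ~50).
#' @param seed integer seed (counts substream derived by fixed offset).
#' @return list with `counts` (gene-by-sample tibble, headers
#'   `region:replicate`) and `truth` (list with the planted `de` table,
#'   `size_factors`, `dispersion` and `baseline_mean`).
#' @export
simulate_region_counts <- function(genes = 2000,
                                   n_per_region = 3,
                                   de = NULL,
                                   dispersion = 0.1,
                                   size_factors = 1,
                                   baseline_log_mean = log(50),
                                   baseline_log_sd = 1,
                                   seed = 0) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("GENE%04d", seq_len(genes))
  }
  genes <- as.character(genes)
  n_genes <- length(genes)
  regions <- c("Bulk", "CC", "ST")
  if (length(n_per_region) == 1) {
    n_per_region <- stats::setNames(rep(n_per_region, 3), regions)
  }
  if (!all(regions %in% names(n_per_region)) || any(n_per_region < 2)) {
    abort("n_per_region must give >= 2 replicates for each of Bulk, CC, ST")
  }
  if (any(dispersion <= 0)) abort("dispersion must be > 0")
  if (any(size_factors <= 0)) abort("size_factors must be > 0")

  lfc <- matrix(0, nrow = n_genes, ncol = 3,
                dimnames = list(genes, regions))
  if (!is.null(de) && nrow(de) > 0) {
    stopifnot(all(c("gene", "region", "log2fc") %in% names(de)))
    if (!all(de$region %in% c("CC", "ST"))) {
      abort("planted regions must be 'CC' or 'ST' (effects are vs Bulk)")
    }
    if (!all(de$gene %in% genes)) abort("planted genes must be in `genes`")
    if (any(!is.finite(de$log2fc))) abort("planted log2fc must be finite")
    lfc[cbind(match(de$gene, genes), match(de$region, regions))] <- de$log2fc
  }

  samples <- unlist(lapply(regions, function(r) {
    paste0(r, ":", seq_len(n_per_region[[r]]))
  }))
  sample_region <- sub(":.*", "", samples)
  sf <- rep_len(size_factors, length(samples))
  disp <- rep_len(dispersion, n_genes)

  m <- with_seed(substream_seed(seed, "counts"), {
    base <- rlnorm(n_genes, baseline_log_mean, baseline_log_sd)
    out <- matrix(0L, nrow = n_genes, ncol = length(samples))
    for (j in seq_along(samples)) {
      mu <- base * 2^lfc[, sample_region[j]] * sf[j]
      out[, j] <- rnbinom(n_genes, mu = mu, size = 1 / disp)
    }
    attr(out, "baseline_mean") <- base
    out
  })
  base <- attr(m, "baseline_mean")
  attr(m, "baseline_mean") <- NULL
  colnames(m) <- samples
  rownames(m) <- genes
  counts <- matrix_to_tbl(m)
  counts[-1] <- lapply(counts[-1], as.integer)

  list(
    counts = counts,
    truth = list(
      de = if (is.null(de)) tibble::tibble(gene = character(),
                                           region = character(),
                                           log2fc = numeric()) else de,
      size_factors = stats::setNames(sf, samples),
      dispersion = disp,
      baseline_mean = stats::setNames(base, genes)
    )
  )
}
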
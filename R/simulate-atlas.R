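#' Simulate a reference expression atlas with planted cell-type markers
#'
#' Generates an FPKM-like, log-normal expression matrix over several cell
#' types with replicates. A set of marker genes per cell type is elevated by
#' `marker_effect` (log2 units) in its own type; all genes carry log-scale
#' Gaussian noise of sd `noise_sd`. The planted gene-to-type assignment is
#' returned as ground truth so that downstream signature derivation can be
#' scored against it.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param n_markers_per_type planted marker genes per cell type.
#' @param n_background_genes genes with no type preference.
#' @param n_replicates replicates per cell type (>= 2).
#' @param marker_effect log2-scale elevation of a marker in its own type
#'   (> 0). Default 2 (a 4-fold elevation).
#' @param noise_sd log2-scale noise sd (>= 0). Default 0.5, giving the
#'   4-to-1 effect-to-noise ratio at which signature recovery is expected
#'   to be essentially complete.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale distribution of
#'   per-gene baseline expression.
#' @param seed integer seed; the atlas substream is derived from it by a
#'   fixed offset, so identical seeds give byte-identical output.
#' @return list with `expression` (gene-by-sample tibble, headers
#'   `celltype:replicate`) and `truth` (tibble `gene`, `cell_type`, with
#'   `"none"` for background genes, plus the generator parameters as
#'   attributes).
#' @export
simulate_atlas <- function(n_cell_types = 3, n_markers_per_type = 50,
                           n_background_genes = 500, n_replicates = 3,
                           marker_effect = 2, noise_sd = 0.5,
                           baseline_log2_mean = 3, baseline_log2_sd = 1,
                           seed = 0) {
  if (n_cell_types < 2) abort("n_cell_types must be >= 2")
  if (n_replicates < 2) abort("n_replicates must be >= 2")
  if (n_markers_per_type < 1 || n_background_genes < 0) {
    abort("gene counts must be positive")
  }
  check_number(marker_effect, "marker_effect", lower = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)

  types <- paste0("TYPE", seq_len(n_cell_types))
  n_genes <- n_cell_types * n_markers_per_type + n_background_genes
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  cell_type <- c(rep(types, each = n_markers_per_type),
                 rep("none", n_background_genes))

  samples <- as.vector(outer(types, seq_len(n_replicates),
                             function(t, r) paste0(t, ":", r)))
  sample_type <- sub(":.*", "", samples)

  m <- with_seed(substream_seed(seed, "atlas"), {
    base <- rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
    log2v <- matrix(base, nrow = n_genes, ncol = length(samples))
    for (j in seq_along(samples)) {
      elev <- ifelse(cell_type == sample_type[j], marker_effect, 0)
      log2v[, j] <- log2v[, j] + elev +
        if (noise_sd > 0) rnorm(n_genes, 0, noise_sd) else 0
    }
    2^log2v
  })
  colnames(m) <- samples
  rownames(m) <- genes

  truth <- tibble::tibble(gene = genes, cell_type = cell_type)
  attr(truth, "marker_effect") <- marker_effect
  attr(truth, "noise_sd") <- noise_sd
  list(expression = matrix_to_tbl(m), truth = truth)
}
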
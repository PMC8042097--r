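#' Cell-type gene-signature sets
#'
#' A `wm_signatures` object is a named list of character gene vectors, one per
#' cell type or state, with provenance attributes recording how it was derived
#' (CV cutoff, number of K-means clusters, discrimination margin). Signatures
#' are GMT-serialisable via [write_gmt()].
#'
#' @param sets named list of character vectors (no empty signature, genes
#'   unique within a signature).
#' @param provenance optional named list stored as an attribute.
#' @return a `wm_signatures` object.
#' @export
new_wm_signatures <- function(sets, provenance = list()) {
  stopifnot(is.list(sets))
  if (length(sets) > 0) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      abort("every signature must be named")
    }
    if (anyDuplicated(names(sets))) abort("duplicate signature names")
    if (any(lengths(sets) == 0)) abort("empty signatures are not allowed")
    sets <- lapply(sets, function(g) unique(as.character(g)))
  }
  structure(sets, provenance = provenance, class = "wm_signatures")
}

as_signature_list <- function(x) {
  if (inherits(x, "wm_signatures")) return(unclass(x))
  if (is.list(x) && !is.null(names(x))) return(lapply(x, as.character))
  abort("expected a wm_signatures object or a named list of gene vectors")
}

#' @export
print.wm_signatures <- function(x, ...) {
  cat(sprintf("<wm_signatures> %d signature(s)\n", length(x)))
  for (nm in names(x)) {
    genes <- x[[nm]]
    shown <- paste(head(genes, 6), collapse = ", ")
    if (length(genes) > 6) shown <- paste0(shown, ", ...")
    cat(sprintf("  %s (%d): %s\n", nm, length(genes), shown))
  }
  invisible(x)
}

#' @export
tidy.wm_signatures <- function(x, ...) {
  if (length(x) == 0) {
    return(tibble::tibble(signature = character(), gene = character()))
  }
  tibble::tibble(
    signature = rep(names(x), lengths(x)),
    gene = unlist(x, use.names = FALSE)
  )
}

#' Preprocess a reference atlas
#'
#' Standard cleanup of a reference expression atlas ahead of signature
#' derivation: gene identifiers are upper-cased, duplicate gene entries are
#' collapsed by arithmetic mean, low-coverage genes (maximum condition mean
#' below `low_coverage_min`) are removed, condition replicates are averaged,
#' values are (optionally) log2-transformed and each gene row is
#' median-centred. Median-centring is idempotent: preprocessing twice equals
#' preprocessing once.
#'
#' @param atlas gene-by-sample tibble (columns `gene` then
#'   `celltype:replicate` samples) of nonnegative expression values.
#' @param low_coverage_min genes whose maximum condition mean (on the input
#'   scale) is below this are dropped. Default 1 expression unit.
#' @param log2_transform apply `log2(x + 1)` after replicate averaging and
#'   before centring (default `TRUE`). Already-centred input (any negative
#'   values) is never re-transformed.
#' @return tibble with columns `gene` then one column per condition, rows
#'   median-centred.
#' @export
preprocess_atlas <- function(atlas, low_coverage_min = 1, log2_transform = TRUE) {
  stopifnot(is.data.frame(atlas), "gene" %in% names(atlas))
  atlas$gene <- toupper(atlas$gene)
  m <- as_expr_matrix(atlas)
  if (any(!is.finite(m))) abort("atlas values must be finite")
  info <- parse_sample_labels(colnames(m))
  if (anyDuplicated(info[c("condition", "replicate")])) {
    abort("duplicate (condition, replicate) sample labels")
  }

  # collapse duplicate gene ids by arithmetic mean
  if (anyDuplicated(rownames(m))) {
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(rownames(m))[unique(rownames(m))])
  }

  # average replicates per condition
  cm <- condition_means(m, info)

  # centred data (negative values) is already preprocessed: re-filtering or
  # re-transforming it would not be idempotent
  already_centred <- any(cm < 0)
  if (!already_centred) {
    keep <- apply(cm, 1, max) >= low_coverage_min
    if (!any(keep)) {
      abort(sprintf(
        "no gene survives the low-coverage filter (max condition mean >= %g)",
        low_coverage_min
      ))
    }
    cm <- cm[keep, , drop = FALSE]
    if (log2_transform) cm <- log2(cm + 1)
  }
  cm <- cm - apply(cm, 1, median)
  matrix_to_tbl(cm)
}

#' Select variable genes by coefficient of variation
#'
#' CV (sample sd / mean) is computed on condition-averaged, non-centred
#' values: a median-centred row has mean near zero, where sd/mean is
#' meaningless, so selection always works on the positive expression scale.
#' Genes with zero mean are excluded with a message. CV is scale-invariant,
#' so multiplying the atlas by any positive constant changes no decision.
#'
#' @param atlas gene-by-sample tibble on the expression scale (replicates are
#'   averaged per condition internally; duplicate gene ids collapsed by mean).
#' @param cv_cutoff keep genes with CV strictly greater than this. The
#'   cutoff is dataset-dependent (published atlas analyses have used values
#'   from 0.1 to 1.5).
#' @return character vector of gene ids, input order preserved.
#' @export
select_variable_genes <- function(atlas, cv_cutoff) {
  check_number(cv_cutoff, "cv_cutoff", lower = 0)
  atlas$gene <- toupper(atlas$gene)
  m <- as_expr_matrix(atlas)
  if (any(m < 0)) {
    abort("select_variable_genes() expects non-centred expression values")
  }
  info <- parse_sample_labels(colnames(m))
  if (anyDuplicated(rownames(m))) {
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(rownames(m))[unique(rownames(m))])
  }
  cm <- condition_means(m, info)

  mu <- rowMeans(cm)
  zero <- mu == 0
  if (any(zero)) {
    inform(sprintf(
      "%d gene(s) with zero mean excluded from CV selection", sum(zero)
    ))
  }
  cv <- apply(cm, 1, sd) / mu
  rownames(m)[!zero & is.finite(cv) & cv > cv_cutoff]
}

#' Derive cell-type signatures by K-means clustering
#'
#' The selected genes are K-means-clustered on their centred condition
#' profiles. A cluster becomes the signature of cell type `T` when its mean
#' profile is maximal at `T` and exceeds the second-highest condition by at
#' least `margin`; clusters failing this discrimination rule are discarded,
#' and when several clusters qualify for the same cell type only the one with
#' the largest margin is kept. K-means is restarted `nstart` times from a
#' fixed seed and the lowest within-cluster sum of squares wins, so results
#' are reproducible and invariant to sample order.
#'
#' @param centred tibble from [preprocess_atlas()] (columns `gene` then one
#'   per condition).
#' @param genes genes to cluster (subset of `centred$gene`), typically from
#'   [select_variable_genes()].
#' @param k number of clusters; defaults to twice the number of conditions,
#'   which leaves room for non-discriminating clusters when the CV cutoff is
#'   permissive. With a stringent cutoff that retains mostly markers, `k`
#'   equal to the number of cell types is the better choice.
#' @param margin minimum lead of the top condition over the runner-up in the
#'   cluster mean profile, in centred log2 units. Default 0.5 (about 1.4-fold).
#' @param seed integer seed for the K-means restarts.
#' @param nstart number of K-means restarts (default 10).
#' @return a [wm_signatures] object (possibly empty, with a warning, when no
#'   cluster passes the margin rule).
#' @export
derive_signatures <- function(centred, genes, k = NULL, margin = 0.5,
                              seed = 0, nstart = 10) {
  stopifnot(is.data.frame(centred), "gene" %in% names(centred))
  genes <- toupper(genes)
  missing <- setdiff(genes, centred$gene)
  if (length(missing) > 0) {
    abort(sprintf("genes not present in the centred atlas: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  m <- as_expr_matrix(centred)[genes, , drop = FALSE]
  if (is.null(k)) k <- 2L * ncol(m)
  if (k > nrow(m)) {
    abort(sprintf("k = %d exceeds the number of genes to cluster (%d)",
                  k, nrow(m)))
  }
  check_number(margin, "margin", lower = 0)

  km <- with_seed(seed, kmeans(m, centers = k, nstart = nstart, iter.max = 100))

  conds <- colnames(m)
  assigned <- list()
  margins <- numeric(0)
  for (cl in seq_len(k)) {
    profile <- km$centers[cl, ]
    ord <- order(profile, decreasing = TRUE)
    lead <- profile[ord[1]] - profile[ord[2]]
    if (lead >= margin) {
      ct <- conds[ord[1]]
      if (is.null(assigned[[ct]]) || lead > margins[[ct]]) {
        assigned[[ct]] <- genes[km$cluster == cl]
        margins[[ct]] <- lead
      }
    }
  }
  if (length(assigned) == 0) {
    warn("no cluster passed the discrimination margin; returning an empty set")
  }
  new_wm_signatures(
    assigned[order(match(names(assigned), conds))],
    provenance = list(k = k, margin = margin, seed = seed)
  )
}
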
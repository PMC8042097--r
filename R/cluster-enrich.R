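#' Select regulated genes and K-means-cluster their region profiles
#'
#' Genes passing `p_adj < alpha` and `|log2_ratio| > lfc_min` (both strict)
#' in at least one of the two region comparisons are clustered by K-means on
#' their (CC ratio, ST ratio) vectors. Defaults mirror the standard
#' region-infiltration analysis: ratio threshold 0.58 (1.5-fold), 7 clusters.
#'
#' @param de_cc,de_st `wm_de` results for the white-matter (CC vs Bulk) and
#'   grey-matter (ST vs Bulk) comparisons, sharing a gene universe.
#' @param lfc_min minimum absolute log2 ratio (strict).
#' @param alpha adjusted-p threshold (strict); default 0.1, the threshold
#'   used for this selection step in region-infiltration analyses (a
#'   stricter 0.05 variant also appears in the literature and can be set
#'   here).
#' @param k number of K-means clusters.
#' @param seed seed for the K-means restarts.
#' @param nstart number of restarts (lowest within-cluster SS wins).
#' @return tibble `gene`, `log2_ratio_cc`, `log2_ratio_st`, `cluster`
#'   (factor `C1`..`Ck`).
#' @export
select_and_cluster <- function(de_cc, de_st, lfc_min = 0.58, alpha = 0.1,
                               k = 7, seed = 0, nstart = 10) {
  if (!setequal(de_cc$gene, de_st$gene)) {
    abort("the two comparisons must share a gene universe")
  }
  merged <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(de_cc), "gene",
                  log2_ratio_cc = "log2_ratio", p_adj_cc = "p_adj"),
    dplyr::select(tibble::as_tibble(de_st), "gene",
                  log2_ratio_st = "log2_ratio", p_adj_st = "p_adj"),
    by = "gene"
  )
  pass <- with(merged,
               (!is.na(p_adj_cc) & p_adj_cc < alpha & abs(log2_ratio_cc) > lfc_min) |
               (!is.na(p_adj_st) & p_adj_st < alpha & abs(log2_ratio_st) > lfc_min))
  sel <- merged[pass, ]
  if (nrow(sel) < k) {
    abort(sprintf(
      "only %d genes selected but k = %d; use a smaller k", nrow(sel), k
    ))
  }
  km <- with_seed(seed, kmeans(as.matrix(sel[c("log2_ratio_cc", "log2_ratio_st")]),
                               centers = k, nstart = nstart, iter.max = 100))
  dplyr::mutate(
    dplyr::select(sel, "gene", "log2_ratio_cc", "log2_ratio_st"),
    cluster = factor(paste0("C", km$cluster),
                     levels = paste0("C", seq_len(k)))
  )
}

#' One-sided Fisher exact enrichment of gene groups in signatures
#'
#' For each (group, signature) pair, the upper tail of the hypergeometric
#' distribution of the overlap given the universe — i.e. a one-sided Fisher
#' exact test for over-representation. Groups and signatures are intersected
#' with the universe before testing. Correction (Benjamini-Hochberg by
#' default, Bonferroni optionally) is applied across all cells of the
#' matrix. The percentage of each group falling in the signature is also
#' reported, matching how such overlaps are plotted.
#'
#' @param gene_groups named list of gene vectors (e.g. split from
#'   [select_and_cluster()] output), or a tibble with columns `gene` and
#'   `cluster`.
#' @param signatures a [wm_signatures] object or named list.
#' @param universe character vector of genes (commonly the genes surviving
#'   [filter_counts()]).
#' @param correction `"bh"` or `"bonferroni"`.
#' @return a `wm_enrichment` tibble: `group`, `signature`, `universe_size`,
#'   `group_size`, `signature_size`, `overlap`, `pct_of_group`,
#'   `odds_ratio`, `p`, `p_adj`, `neg_log10_p_adj`.
#' @export
enrich <- function(gene_groups, signatures, universe,
                   correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  if (is.data.frame(gene_groups)) {
    stopifnot(all(c("gene", "cluster") %in% names(gene_groups)))
    gene_groups <- split(gene_groups$gene, gene_groups$cluster, drop = FALSE)
  }
  sets <- as_signature_list(signatures)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty universe")
  if (length(gene_groups) == 0 || any(lengths(gene_groups) == 0)) {
    abort("gene groups must be non-empty")
  }

  groups <- lapply(gene_groups, function(g) intersect(unique(g), universe))
  sigs <- lapply(sets, function(g) intersect(unique(g), universe))
  disjoint <- names(sigs)[lengths(sigs) == 0]
  if (length(disjoint) > 0) {
    warn(sprintf("signature(s) disjoint from the universe: %s",
                 paste(disjoint, collapse = ", ")))
  }

  N <- length(universe)
  res <- tidyr::expand_grid(group = names(groups), signature = names(sigs))
  res <- dplyr::mutate(
    res,
    universe_size = N,
    group_size = unname(lengths(groups)[.data$group]),
    signature_size = unname(lengths(sigs)[.data$signature]),
    overlap = purrr::map2_int(.data$group, .data$signature, function(g, s) {
      length(intersect(groups[[g]], sigs[[s]]))
    }),
    pct_of_group = 100 * .data$overlap / .data$group_size,
    odds_ratio = {
      a <- .data$overlap
      b <- .data$group_size - a
      cc <- .data$signature_size - a
      d <- N - .data$group_size - cc
      (a * d) / (b * cc)
    },
    p = phyper(.data$overlap - 1, .data$signature_size,
               N - .data$signature_size, .data$group_size,
               lower.tail = FALSE),
    p_adj = p.adjust(.data$p, method = if (correction == "bh") "BH" else "bonferroni"),
    neg_log10_p_adj = -log10(.data$p_adj)
  )
  structure(res,
            correction = correction,
            class = c("wm_enrichment", class(res)))
}

#' @export
glance.wm_enrichment <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_groups = dplyr::n_distinct(x$group),
    n_signatures = dplyr::n_distinct(x$signature),
    n_enriched = sum(x$p_adj < alpha),
    correction = attr(x, "correction"),
    top_group = x$group[which.min(x$p_adj)],
    top_signature = x$signature[which.min(x$p_adj)]
  )
}

#' Regulated members of each signature in a comparison
#'
#' Lists, per signature, the member genes significantly regulated
#' (`p_adj < alpha`, default 0.1) in a differential-expression result, with
#' their log2 ratios and direction — the table behind stage-ordered marker
#' panels. Signatures with no regulated member are retained as a single row
#' with an NA gene.
#'
#' @param de a `wm_de` result.
#' @param signatures a [wm_signatures] object or named list.
#' @param alpha adjusted-p threshold (strict).
#' @return tibble `signature`, `gene`, `log2_ratio`, `p_adj`, `direction`
#'   (`up`/`down`), ordered by signature then descending ratio.
#' @export
signature_regulation_summary <- function(de, signatures, alpha = 0.1) {
  sets <- as_signature_list(signatures)
  de_tbl <- tibble::as_tibble(de)
  purrr::map_dfr(names(sets), function(nm) {
    hits <- dplyr::filter(
      de_tbl, .data$gene %in% sets[[nm]],
      !is.na(.data$p_adj), .data$p_adj < alpha
    )
    if (nrow(hits) == 0) {
      return(tibble::tibble(signature = nm, gene = NA_character_,
                            log2_ratio = NA_real_, p_adj = NA_real_,
                            direction = NA_character_))
    }
    hits <- dplyr::arrange(hits, dplyr::desc(.data$log2_ratio))
    tibble::tibble(
      signature = nm,
      gene = hits$gene,
      log2_ratio = hits$log2_ratio,
      p_adj = hits$p_adj,
      direction = ifelse(hits$log2_ratio > 0, "up", "down")
    )
  })
}
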
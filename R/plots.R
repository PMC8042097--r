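#' Plot sample PCA
#'
#' Scatter of PC1 against PC2, coloured by condition, with variance
#' fractions in the axis labels.
#'
#' @param object a `wm_pca` result from [pca_samples()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wm_pca <- function(object, ...) {
  v <- attr(object, "variance_explained")
  ggplot2::ggplot(object, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data$condition)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * v[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * v[2]),
      colour = "region"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-by-signature enrichment matrix
#'
#' Heatmap of -log10 adjusted p-values, the usual way these overlap
#' matrices are displayed.
#'
#' @param object a `wm_enrichment` result from [enrich()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wm_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$signature, .data$group,
                                       fill = .data$neg_log10_p_adj)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red3",
                                 name = expression(-log[10] ~ p[adj])) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Volcano plot of a differential-expression result
#'
#' @param object a `wm_de` result.
#' @param alpha,lfc_min thresholds drawn and used to colour regulated genes.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wm_de <- function(object, alpha = 0.05, lfc_min = 0.58, ...) {
  d <- dplyr::mutate(
    tibble::as_tibble(object),
    regulated = !is.na(.data$p_adj) & .data$p_adj < alpha &
      abs(.data$log2_ratio) > lfc_min
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_ratio, -log10(.data$p),
                                  colour = .data$regulated)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3"), guide = "none") +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = 2) +
    ggplot2::labs(x = expression(log[2] ~ ratio), y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Plot g-ratio against axon diameter with per-group trend lines
#'
#' @param object a measured axon tibble (from [measure_axons()]) with an
#'   optional grouping column.
#' @param group unquoted grouping column, if any.
#' @return a ggplot object.
#' @export
plot_gratio <- function(object, group = NULL) {
  grp <- enquo(group)
  p <- if (rlang::quo_is_null(grp)) {
    ggplot2::ggplot(object, ggplot2::aes(.data$axon_feret, .data$g_ratio))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$axon_feret, .data$g_ratio,
                                         colour = !!grp))
  }
  p +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "axon Feret diameter (µm)", y = "g-ratio") +
    ggplot2::theme_minimal()
}
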
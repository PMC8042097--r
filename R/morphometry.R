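#' Measure axons: Feret diameters and g-ratios
#'
#' Computes, per axon, the Feret diameter of the axon and of the outer
#' (axon + myelin sheath) contour and the g-ratio (axon Feret divided by
#' outer Feret). Two input modes mirror how EM analysts record data:
#' contour mode (list-columns `axon_contour` / `outer_contour` of `x`, `y`
#' points) and diameter mode (pre-measured `axon_feret` / `outer_feret`
#' columns). A sample with fewer than `min_axons` axons triggers a warning,
#' not an error.
#'
#' @param axons tibble with one row per axon (see Details for columns).
#' @param min_axons minimum recommended axons per analysis (default 50).
#' @return the input with `axon_feret`, `outer_feret` and `g_ratio` columns.
#' @export
measure_axons <- function(axons, min_axons = 50) {
  stopifnot(is.data.frame(axons))
  if (nrow(axons) < min_axons) {
    warn(sprintf("only %d axons; analyses of this kind are usually based on >= %d",
                 nrow(axons), min_axons))
  }
  if (!"axon_feret" %in% names(axons)) {
    if (!all(c("axon_contour", "outer_contour") %in% names(axons))) {
      abort("need either Feret columns or contour list-columns")
    }
    axons$axon_feret <- vapply(axons$axon_contour, feret_diameter, numeric(1))
    axons$outer_feret <- vapply(axons$outer_contour, feret_diameter, numeric(1))
  }
  axons$g_ratio <- g_ratio(axons$axon_feret, axons$outer_feret,
                           axon_id = if ("axon_id" %in% names(axons)) axons$axon_id)
  tibble::as_tibble(axons)
}

#' Myelin g-ratio
#'
#' Axonal diameter divided by the corresponding axonal + myelin sheath
#' diameter. Lies in (0, 1]; equals 1 only for a naked axon (zero sheath
#' thickness); strictly decreases as the sheath thickens at fixed axon size.
#'
#' @param axon_feret,outer_feret diameters (µm), `0 < axon <= outer`.
#' @param axon_id optional ids used in error messages.
#' @return g-ratio values.
#' @export
g_ratio <- function(axon_feret, outer_feret, axon_id = NULL) {
  bad <- !(axon_feret > 0 & outer_feret >= axon_feret)
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    who <- if (!is.null(axon_id)) {
      paste(axon_id[which(bad | is.na(bad))], collapse = ", ")
    } else {
      paste(which(bad | is.na(bad)), collapse = ", ")
    }
    abort(sprintf(
      "need 0 < axon_feret <= outer_feret; violated for axon(s): %s", who
    ))
  }
  axon_feret / outer_feret
}

#' Classify axons as decompacted and/or degenerating
#'
#' An axon has decompacted myelin when strictly more than
#' `decompaction_threshold` (default 15%) of its circumference shows
#' decompaction; it is degenerating when it exhibits any of: condensed
#' axoplasm, organelle accumulation, axonal swelling, vacuoles, dark
#' axoplasm (a non-empty feature set).
#'
#' @param axons tibble with `decompacted_arc_fraction` and a `features`
#'   list-column of character vectors.
#' @param decompaction_threshold circumference fraction (strict `>`).
#' @return the input with logical `decompacted` and `degenerating` columns.
#' @export
classify_axons <- function(axons, decompaction_threshold = 0.15) {
  stopifnot(is.data.frame(axons),
            "decompacted_arc_fraction" %in% names(axons))
  arc <- axons$decompacted_arc_fraction
  if (any(arc < 0 | arc > 1, na.rm = TRUE)) {
    abort("decompacted_arc_fraction must be in [0, 1]")
  }
  feats <- if ("features" %in% names(axons)) axons$features else
    vector("list", nrow(axons))
  dplyr::mutate(
    tibble::as_tibble(axons),
    decompacted = arc > decompaction_threshold,
    degenerating = vapply(feats, function(f) length(f) > 0, logical(1))
  )
}

#' Per-group linear trend of g-ratio versus axon diameter
#'
#' Ordinary least-squares fit of g-ratio on axon Feret diameter within each
#' condition group — the regression line drawn through g-ratio scatter
#' plots. Groups with constant diameters get NA slope and are flagged.
#'
#' @param axons tibble with `g_ratio` and `axon_feret` columns.
#' @param group optional grouping column (unquoted); omit for a single fit.
#' @param min_axons minimum recommended axons per group (warning below it).
#' @return a `wm_gratio_fit` tibble: `group`, `n`, `slope`, `intercept`,
#'   `r_squared`, `mean_g_ratio`, `degenerate_x`.
#' @export
gratio_trend <- function(axons, group = NULL, min_axons = 50) {
  stopifnot(all(c("g_ratio", "axon_feret") %in% names(axons)))
  grp <- enquo(group)
  tbl <- tibble::as_tibble(axons)
  tbl$.group <- if (rlang::quo_is_null(grp)) "all" else
    as.character(dplyr::pull(tbl, !!grp))

  res <- purrr::map_dfr(split(tbl, tbl$.group), function(d) {
    if (nrow(d) < 3) abort("each group needs at least 3 axons")
    if (nrow(d) < min_axons) {
      warn(sprintf("group '%s' has %d axons (< %d recommended)",
                   d$.group[1], nrow(d), min_axons))
    }
    degenerate <- length(unique(d$axon_feret)) == 1
    if (degenerate) {
      return(tibble::tibble(group = d$.group[1], n = nrow(d),
                            slope = NA_real_, intercept = NA_real_,
                            r_squared = NA_real_,
                            mean_g_ratio = mean(d$g_ratio),
                            degenerate_x = TRUE))
    }
    fit <- lm(g_ratio ~ axon_feret, data = d)
    tss <- sum((d$g_ratio - mean(d$g_ratio))^2)
    r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
    tibble::tibble(
      group = d$.group[1], n = nrow(d),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      mean_g_ratio = mean(d$g_ratio),
      degenerate_x = FALSE
    )
  })
  structure(res, class = c("wm_gratio_fit", class(res)))
}

#' @export
tidy.wm_gratio_fit <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.wm_gratio_fit <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x), n_axons = sum(x$n),
                 mean_g_ratio = sum(x$mean_g_ratio * x$n) / sum(x$n))
}
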
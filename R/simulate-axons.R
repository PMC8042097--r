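#' Simulate myelinated axon cross-sections for morphometry
#'
#' Each axon is an ellipse-like cross-section (polygonal contour) with a
#' concentric myelin sheath of constant thickness, so the outer contour is
#' the axon ellipse grown by the sheath thickness. A chosen fraction of
#' axons carries myelin decompaction over more than 15% of the circumference
#' and a chosen fraction carries degeneration features; flagged counts are
#' honoured exactly (rounded to the nearest count).
#'
#' @param n number of axons.
#' @param radius_range range (µm) of the axon semi-major axis.
#' @param myelin_thickness_range range (µm) of sheath thickness (> 0).
#' @param decompacted_fraction,degenerating_fraction fractions in `[0, 1]`.
#' @param aspect_range range of the minor/major axis ratio (1 = circle).
#' @param n_contour_points polygon vertices per contour (even, so antipodal
#'   vertices make the polygon Feret equal the true major diameter).
#' @param seed integer seed (axons substream derived by fixed offset).
#' @return tibble with one row per axon: `axon_id`, list-columns
#'   `axon_contour` and `outer_contour` (tibbles of `x`, `y` in µm),
#'   `decompacted_arc_fraction`, `features` (list of character),
#'   and the planted truth flags `true_decompacted`, `true_degenerating`.
#' @export
simulate_axons <- function(n, radius_range = c(0.3, 1.2),
                           myelin_thickness_range = c(0.08, 0.3),
                           decompacted_fraction = 0,
                           degenerating_fraction = 0,
                           aspect_range = c(0.7, 1),
                           n_contour_points = 64,
                           seed = 0) {
  if (n < 1) abort("n must be >= 1")
  if (any(radius_range <= 0) || diff(radius_range) < 0) {
    abort("radius_range must be positive and increasing")
  }
  if (any(myelin_thickness_range <= 0) || diff(myelin_thickness_range) < 0) {
    abort("myelin thickness must be > 0")
  }
  for (f in c(decompacted_fraction, degenerating_fraction)) {
    if (f < 0 || f > 1) abort("fractions must be in [0, 1]")
  }
  if (n_contour_points %% 2 != 0) abort("n_contour_points must be even")

  degeneration_features <- c("condensed axoplasm", "organelle accumulation",
                             "axonal swelling", "vacuoles", "dark axoplasm")
  n_dec <- round(n * decompacted_fraction)
  n_deg <- round(n * degenerating_fraction)

  with_seed(substream_seed(seed, "axons"), {
    a <- runif(n, radius_range[1], radius_range[2])
    b <- a * runif(n, aspect_range[1], aspect_range[2])
    thick <- runif(n, myelin_thickness_range[1], myelin_thickness_range[2])
    rot <- runif(n, 0, pi)
    cx <- runif(n, 0, 50)
    cy <- runif(n, 0, 50)

    dec <- seq_len(n) %in% sample.int(n, n_dec)
    deg <- seq_len(n) %in% sample.int(n, n_deg)
    arc <- ifelse(dec, runif(n, 0.16, 0.6), runif(n, 0, 0.15))
    feats <- lapply(seq_len(n), function(i) {
      if (deg[i]) sample(degeneration_features, sample.int(2, 1)) else character(0)
    })

    theta <- seq(0, 2 * pi, length.out = n_contour_points + 1)[-(n_contour_points + 1)]
    contour <- function(i, grow) {
      x0 <- (a[i] + grow) * cos(theta)
      y0 <- (b[i] + grow) * sin(theta)
      tibble::tibble(
        x = cx[i] + x0 * cos(rot[i]) - y0 * sin(rot[i]),
        y = cy[i] + x0 * sin(rot[i]) + y0 * cos(rot[i])
      )
    }

    tibble::tibble(
      axon_id = sprintf("AX%03d", seq_len(n)),
      axon_contour = lapply(seq_len(n), function(i) contour(i, grow = 0)),
      outer_contour = lapply(seq_len(n), function(i) contour(i, grow = thick[i])),
      decompacted_arc_fraction = arc,
      features = feats,
      true_decompacted = dec,
      true_degenerating = deg
    )
  })
}
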
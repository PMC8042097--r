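#' Simulate a 2-D cell field with marker intensities and axon paths
#'
#' Emulates the measurement tables extracted from stained sections: cells
#' with positions, nucleus radii, per-marker mean-grey intensities and an ROI
#' label, alongside Neurofilament-like axon polylines and a tumour-bulk
#' polygon. Ground truth (intensity tier, marker positivity, axon contact
#' under the supplied distance rule) is recorded per cell so downstream
#' classifiers can be scored exactly.
#'
#' Intensities for the tiered marker are drawn uniformly from per-tier bands.
#' Overlapping bands are allowed (real stains overlap) but flagged in the
#' truth metadata, since perfect tier recovery is only guaranteed for
#' disjoint bands.
#'
#' @param n_cells number of cells.
#' @param positive_fraction fraction of cells positive for the tiered marker;
#'   the positive count is `round(n_cells * positive_fraction)` exactly.
#' @param tier_bands named list of `c(min, max)` intensity bands for tiers
#'   `negative`, `low`, `high`. Positive cells split evenly between `low`
#'   and `high`.
#' @param background background mean-grey value (cells below it are negative
#'   by construction when the default bands are used).
#' @param n_axon_paths number of axon polylines laid across the field.
#' @param field_size side length (µm) of the square field.
#' @param nucleus_radius_range range (µm) of nucleus radii.
#' @param contact_distance the contact rule (µm) used to record truth labels.
#' @param bulk_polygon tumour-bulk outline (data frame `x`, `y`); default is
#'   a square occupying the lower-left quadrant of the field.
#' @param seed integer seed (cells substream derived by fixed offset).
#' @return list with `cells` (tibble: `cell_id`, `x`, `y`, `nucleus_radius`,
#'   `intensity`, `roi`), `axon_paths` (tibble: `path_id`, `x`, `y`),
#'   `bulk_polygon`, and `truth` (tibble: `cell_id`, `tier`, `positive`,
#'   `contact`; attribute `bands_overlap`).
#' @export
simulate_cell_field <- function(n_cells = 200,
                                positive_fraction = 0.5,
                                tier_bands = list(negative = c(0, 15),
                                                  low = c(30, 60),
                                                  high = c(80, 120)),
                                background = 20,
                                n_axon_paths = 8,
                                field_size = 200,
                                nucleus_radius_range = c(2.5, 4.5),
                                contact_distance = 1.5,
                                bulk_polygon = NULL,
                                seed = 0) {
  if (positive_fraction < 0 || positive_fraction > 1) {
    abort("positive_fraction must be in [0, 1]")
  }
  stopifnot(all(c("negative", "low", "high") %in% names(tier_bands)))
  bands <- do.call(rbind, tier_bands[c("negative", "low", "high")])
  if (any(bands[, 2] < bands[, 1]) || any(diff(bands[, 1]) < 0)) {
    abort("tier bands must be ordered negative < low < high")
  }
  bands_overlap <- bands[1, 2] > bands[2, 1] || bands[2, 2] > bands[3, 1]
  if (bands_overlap) warn("tier intensity bands overlap; flagged in truth")

  if (is.null(bulk_polygon)) {
    bulk_polygon <- tibble::tibble(
      x = c(0, field_size / 2, field_size / 2, 0),
      y = c(0, 0, field_size / 2, field_size / 2)
    )
  }

  n_pos <- round(n_cells * positive_fraction)
  with_seed(substream_seed(seed, "cells"), {
    x <- runif(n_cells, 0, field_size)
    y <- runif(n_cells, 0, field_size)
    r <- runif(n_cells, nucleus_radius_range[1], nucleus_radius_range[2])

    tier <- rep("negative", n_cells)
    pos_idx <- sample.int(n_cells, n_pos)
    tier[pos_idx] <- sample(rep_len(c("low", "high"), n_pos))
    intensity <- vapply(tier, function(tt) {
      runif(1, tier_bands[[tt]][1], tier_bands[[tt]][2])
    }, numeric(1), USE.NAMES = FALSE)

    paths <- purrr::map_dfr(seq_len(n_axon_paths), function(k) {
      npts <- sample(3:6, 1)
      tibble::tibble(
        path_id = sprintf("AXP%02d", k),
        x = cumsum(c(runif(1, 0, field_size), runif(npts - 1, -30, 30))),
        y = cumsum(c(runif(1, 0, field_size), runif(npts - 1, -30, 30)))
      )
    })

    contact <- vapply(seq_len(n_cells), function(i) {
      dmin <- min(vapply(split(paths, paths$path_id), function(pp) {
        point_polyline_distance(x[i], y[i], pp[, c("x", "y")])
      }, numeric(1)))
      (dmin - r[i]) < contact_distance
    }, logical(1))

    cells <- tibble::tibble(
      cell_id = sprintf("CELL%04d", seq_len(n_cells)),
      x = x, y = y, nucleus_radius = r,
      intensity = intensity,
      roi = ifelse(points_in_polygon(x, y, bulk_polygon), "bulk", "margin")
    )
    truth <- tibble::tibble(
      cell_id = cells$cell_id,
      tier = factor(tier, levels = c("negative", "low", "high")),
      positive = tier != "negative",
      contact = contact
    )
    attr(truth, "bands_overlap") <- bands_overlap
    list(cells = cells, axon_paths = paths,
         bulk_polygon = bulk_polygon, truth = truth)
  })
}
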
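#' Percent positive cells per region of interest
#'
#' The workhorse immunostaining quantification: within each ROI, 100 times
#' the number of cells positive for a marker over the number positive for a
#' denominator marker (e.g. %SOX10+ among HuNu+ tumour cells). ROIs whose
#' denominator count falls below `min_cells` are excluded with a warning —
#' the convention that, say, at least 750 counted cells are required before
#' a region is quantified. A pooled row (totals across retained ROIs) is
#' appended; the pooled percentage always lies between the per-ROI extremes.
#'
#' @param cells tibble with one row per cell.
#' @param positive logical column (unquoted) marking positivity for the
#'   quantified marker.
#' @param denominator optional logical column for the denominator marker;
#'   default: all cells count.
#' @param roi ROI label column (unquoted; default `roi`).
#' @param min_cells minimum denominator cells per ROI.
#' @return tibble `roi`, `n_denominator`, `n_positive`, `pct` with a final
#'   `"pooled"` row; excluded ROIs are recorded in the `"excluded"`
#'   attribute.
#' @export
percent_positive <- function(cells, positive, denominator = NULL,
                             roi = roi, min_cells = 750) {
  stopifnot(is.data.frame(cells))
  den_q <- enquo(denominator)
  tbl <- tibble::tibble(
    roi = as.character(dplyr::pull(cells, {{ roi }})),
    pos = dplyr::pull(cells, {{ positive }}),
    den = if (rlang::quo_is_null(den_q)) TRUE else dplyr::pull(cells, !!den_q)
  )
  if (!is.logical(tbl$pos) || !is.logical(tbl$den)) {
    abort("positivity columns must be logical")
  }
  tbl <- dplyr::filter(tbl, .data$den)
  per_roi <- dplyr::summarise(
    dplyr::group_by(tbl, .data$roi),
    n_denominator = dplyr::n(),
    n_positive = sum(.data$pos),
    .groups = "drop"
  )
  excluded <- per_roi$roi[per_roi$n_denominator < min_cells]
  if (length(excluded) > 0) {
    warn(sprintf("ROI(s) excluded (fewer than %d denominator cells): %s",
                 min_cells, paste(excluded, collapse = ", ")))
  }
  kept <- dplyr::filter(per_roi, !.data$roi %in% excluded)
  kept <- dplyr::mutate(kept, pct = 100 * .data$n_positive / .data$n_denominator)
  pooled <- tibble::tibble(
    roi = "pooled",
    n_denominator = sum(kept$n_denominator),
    n_positive = sum(kept$n_positive),
    pct = 100 * sum(kept$n_positive) / sum(kept$n_denominator)
  )
  structure(dplyr::bind_rows(kept, pooled), excluded = excluded)
}

#' Tier cells by nuclear marker intensity
#'
#' Two tiering rules used for SOX10 mean-grey values:
#'
#' * `mode = "percentile"`: low and high thresholds are the 25th and 75th
#'   percentiles of reference intensities measured across at least
#'   `min_reference` (default 100) nuclei in the tumour bulk. A cell is
#'   `low` when its intensity is at or below the 25th percentile, `high` at
#'   or above the 75th, otherwise `medium`. Labels are stable under any
#'   positive rescaling of all intensities.
#' * `mode = "reference"`: a cell is `negative` when its intensity is
#'   strictly below the image background, `high` when at or above the
#'   minimum intensity of at least `min_high_reference` (default 20) cells
#'   independently judged high, otherwise `low`.
#'
#' @param cells tibble with an intensity column.
#' @param intensity intensity column (unquoted; default `intensity`).
#' @param mode `"percentile"` or `"reference"`.
#' @param reference_intensities numeric vector of bulk reference intensities
#'   (percentile mode); default: the cells' own intensities.
#' @param probs the two percentile cut points (default `c(0.25, 0.75)`).
#' @param background background mean-grey value (reference mode).
#' @param high_reference intensities of the manually identified high cells
#'   (reference mode).
#' @param min_reference,min_high_reference minimum reference cell counts.
#' @return the input with a `tier` factor column (`negative`/`low`/
#'   `medium`/`high` as applicable); thresholds in the `"thresholds"`
#'   attribute.
#' @export
tier_by_intensity <- function(cells, intensity = intensity,
                              mode = c("percentile", "reference"),
                              reference_intensities = NULL,
                              probs = c(0.25, 0.75),
                              background = NULL, high_reference = NULL,
                              min_reference = 100, min_high_reference = 20) {
  mode <- match.arg(mode)
  v <- dplyr::pull(cells, {{ intensity }})
  if (any(v < 0)) abort("intensities must be nonnegative")

  if (mode == "percentile") {
    ref <- if (is.null(reference_intensities)) v else reference_intensities
    if (length(ref) < min_reference) {
      abort(sprintf(
        "percentile tiering requires >= %d reference nuclei (got %d)",
        min_reference, length(ref)
      ))
    }
    q <- quantile(ref, probs, names = FALSE)
    tier <- dplyr::case_when(
      v <= q[1] ~ "low",
      v >= q[2] ~ "high",
      TRUE ~ "medium"
    )
    out <- dplyr::mutate(cells, tier = factor(tier, c("low", "medium", "high")))
    return(structure(out, thresholds = c(low = q[1], high = q[2])))
  }

  if (is.null(background)) abort("reference mode needs a background value")
  if (is.null(high_reference) || length(high_reference) < min_high_reference) {
    abort(sprintf(
      "reference mode needs intensities of >= %d known high cells",
      min_high_reference
    ))
  }
  high_min <- min(high_reference)
  tier <- dplyr::case_when(
    v < background ~ "negative",
    v >= high_min ~ "high",
    TRUE ~ "low"
  )
  out <- dplyr::mutate(cells, tier = factor(tier, c("negative", "low", "high")))
  structure(out, thresholds = c(background = background, high = high_min))
}

#' Cell-to-axon contact calls
#'
#' A cell contacts an axon when the distance from the edge of its nucleus
#' (modelled as a disc of `nucleus_radius` about the cell position) to the
#' nearest axon polyline is strictly less than `max_distance` (default
#' 1.5 µm).
#'
#' @param cells tibble with `x`, `y`, `nucleus_radius`.
#' @param axon_paths tibble `path_id`, `x`, `y` (ordered points per path) or
#'   a list of two-column matrices/data frames.
#' @param max_distance contact threshold in µm (strict `<`).
#' @return the input with logical `contact` and numeric `axon_distance`
#'   (nucleus-edge to nearest axon; negative when the axon crosses the
#'   nucleus) columns. An empty path set yields all-`FALSE` with a warning.
#' @export
axon_contact <- function(cells, axon_paths, max_distance = 1.5) {
  stopifnot(all(c("x", "y", "nucleus_radius") %in% names(cells)))
  if (is.data.frame(axon_paths)) {
    axon_paths <- split(axon_paths[c("x", "y")], axon_paths$path_id)
  }
  if (length(axon_paths) == 0) {
    warn("no axon paths supplied; all contact calls are FALSE")
    return(dplyr::mutate(cells, axon_distance = Inf, contact = FALSE))
  }
  d <- vapply(seq_len(nrow(cells)), function(i) {
    min(vapply(axon_paths, function(pp) {
      point_polyline_distance(cells$x[i], cells$y[i], pp)
    }, numeric(1))) - cells$nucleus_radius[i]
  }, numeric(1))
  dplyr::mutate(cells, axon_distance = d, contact = d < max_distance)
}

#' Myelin disruption calls from fluoromyelin intensities
#'
#' Mean grey values are normalised to the image's max grey value to absorb
#' intensity variation between images; a white-matter ROI is disrupted when
#' it contains axons **and** its normalised fluoromyelin intensity is
#' strictly below `fraction` (default 25%) of the contralateral intact
#' reference. Without a contralateral reference the normalised intensity is
#' still returned but the disruption call is NA.
#'
#' @param rois tibble with `mean_grey`, `max_grey` and logical `has_axons`.
#' @param contralateral_normalised normalised intensity of the contralateral
#'   intact white matter (single value), or `NA`.
#' @param fraction the disruption fraction (strict `<`).
#' @return the input with `normalised_intensity` and `disrupted` columns.
#' @export
myelin_disruption <- function(rois, contralateral_normalised = NA,
                              fraction = 0.25) {
  stopifnot(all(c("mean_grey", "max_grey", "has_axons") %in% names(rois)))
  if (any(rois$max_grey <= 0)) abort("max_grey must be > 0")
  norm <- rois$mean_grey / rois$max_grey
  disrupted <- if (is.na(contralateral_normalised)) {
    NA
  } else {
    rois$has_axons & (norm < fraction * contralateral_normalised)
  }
  dplyr::mutate(tibble::as_tibble(rois),
                normalised_intensity = norm, disrupted = disrupted)
}

#' Invasion index and migrated distances from the tumour bulk
#'
#' The invasion index is the total area occupied by tumour cells — taken as
#' the convex hull of their positions unless a pre-measured `occupied_area`
#' is supplied — normalised to the perimeter of the tumour-bulk outline, to
#' account for different rates of tumour growth. Each cell's migrated
#' distance is its Euclidean distance to the nearest point of the bulk
#' boundary, 0 for cells inside the bulk.
#'
#' @param cells tibble with `x`, `y` positions of tumour cells.
#' @param bulk_polygon simple polygon (tibble `x`, `y`, vertices in order).
#' @param occupied_area optional externally measured area (µm^2) overriding
#'   the convex hull.
#' @return list with `invasion_index` (µm; NA when fewer than 3 positions
#'   and no area is supplied), `occupied_area`, `bulk_perimeter`, and
#'   `cells` (input plus `inside_bulk`, `migrated_distance`).
#' @export
invasion_metrics <- function(cells, bulk_polygon, occupied_area = NULL) {
  stopifnot(all(c("x", "y") %in% names(cells)))
  perim <- polygon_perimeter(bulk_polygon)
  area <- if (!is.null(occupied_area)) occupied_area else
    convex_hull_area(cells[c("x", "y")])
  inside <- points_in_polygon(cells$x, cells$y, bulk_polygon)
  dist <- vapply(seq_len(nrow(cells)), function(i) {
    if (inside[i]) 0 else
      point_polyline_distance(cells$x[i], cells$y[i], bulk_polygon,
                              closed = TRUE)
  }, numeric(1))
  list(
    invasion_index = if (is.na(area)) NA_real_ else area / perim,
    occupied_area = area,
    bulk_perimeter = perim,
    cells = dplyr::mutate(tibble::as_tibble(cells),
                          inside_bulk = inside, migrated_distance = dist)
  )
}

#' Migration-track metrics
#'
#' Per-track summaries of manually tracked cells: total path length, net
#' displacement (first to last position), straightness
#' (displacement / path length, in `[0, 1]`, 0 for a closed loop) and mean
#' speed (path length / elapsed time).
#'
#' @param tracks tibble with columns `cell_id`, `t`, `x`, `y`; rows are
#'   sorted by time within each track and duplicate timestamps are an error.
#' @return tibble `cell_id`, `n_points`, `path_length`, `net_displacement`,
#'   `straightness`, `mean_speed`.
#' @export
track_metrics <- function(tracks) {
  stopifnot(all(c("cell_id", "t", "x", "y") %in% names(tracks)))
  purrr::map_dfr(split(tibble::as_tibble(tracks), tracks$cell_id), function(d) {
    d <- dplyr::arrange(d, .data$t)
    if (nrow(d) < 2) abort(sprintf("track %s has fewer than 2 points",
                                   d$cell_id[1]))
    if (anyDuplicated(d$t)) {
      abort(sprintf("duplicate timestamps in track %s", d$cell_id[1]))
    }
    steps <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    path <- sum(steps)
    disp <- sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2)
    tibble::tibble(
      cell_id = d$cell_id[1],
      n_points = nrow(d),
      path_length = path,
      net_displacement = disp,
      straightness = if (path == 0) 0 else disp / path,
      mean_speed = path / (d$t[nrow(d)] - d$t[1])
    )
  })
}
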
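# 2-D geometry primitives (µm units, image convention: y increases downward).

as_xy_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  if (!is.matrix(points) || ncol(points) != 2) {
    abort("points must be an n x 2 matrix or a data frame with x and y")
  }
  storage.mode(points) <- "double"
  points
}

#' Feret (maximum caliper) diameter of a point set
#'
#' The maximum pairwise Euclidean distance over the points, computed on the
#' convex hull. Used as the axon diameter because EM cross-sections are not
#' perfect circles.
#'
#' @param points an n x 2 matrix or data frame with columns `x`, `y` (n >= 2).
#' @return the Feret diameter (same units as the coordinates).
#' @export
feret_diameter <- function(points) {
  p <- as_xy_matrix(points)
  if (nrow(p) < 2) abort("feret_diameter() needs at least 2 points")
  if (nrow(p) > 3) {
    hull <- grDevices::chull(p)
    p <- p[hull, , drop = FALSE]
  }
  d2 <- 0
  for (i in seq_len(nrow(p) - 1)) {
    dx <- p[(i + 1):nrow(p), 1] - p[i, 1]
    dy <- p[(i + 1):nrow(p), 2] - p[i, 2]
    d2 <- max(d2, max(dx * dx + dy * dy))
  }
  sqrt(d2)
}

# distance from point (px, py) to segment (ax, ay)-(bx, by); vectorised over
# segments
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 == 0, 0,
              pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2)))
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

# minimum distance from a point to a polyline (open) or polygon (closed)
point_polyline_distance <- function(px, py, path, closed = FALSE) {
  p <- as_xy_matrix(path)
  if (nrow(p) < 2) abort("a path needs at least 2 points")
  idx <- seq_len(nrow(p) - 1)
  d <- min(point_segment_distance(px, py, p[idx, 1], p[idx, 2],
                                  p[idx + 1, 1], p[idx + 1, 2]))
  if (closed && nrow(p) > 2) {
    d <- min(d, point_segment_distance(px, py, p[nrow(p), 1], p[nrow(p), 2],
                                       p[1, 1], p[1, 2]))
  }
  d
}

# shoelace area of a simple polygon (vertices in order, not repeated)
polygon_area <- function(poly) {
  p <- as_xy_matrix(poly)
  if (nrow(p) < 3) abort("a polygon needs at least 3 vertices")
  i <- seq_len(nrow(p))
  j <- c(2:nrow(p), 1)
  abs(sum(p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2])) / 2
}

polygon_perimeter <- function(poly) {
  p <- as_xy_matrix(poly)
  if (nrow(p) < 3) abort("a polygon needs at least 3 vertices")
  j <- c(2:nrow(p), 1)
  sum(sqrt(rowSums((p[j, , drop = FALSE] - p)^2)))
}

# convex hull area of a point set (NA when fewer than 3 points; 0 for a
# degenerate, collinear hull)
convex_hull_area <- function(points) {
  p <- as_xy_matrix(points)
  if (nrow(p) < 3) return(NA_real_)
  hull <- grDevices::chull(p)
  if (length(hull) < 3) return(0)
  polygon_area(p[hull, , drop = FALSE])
}

points_in_polygon <- function(px, py, poly) {
  p <- as_xy_matrix(poly)
  mgcv::in.out(rbind(p, p[1, ]), cbind(px, py))
}
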
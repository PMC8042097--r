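# Independent brute-force oracles used against the package implementations.

# Hypergeometric upper tail P(overlap >= observed) by full enumeration of
# all equally likely draws of `group_size` genes from a universe of size N
# containing `sig_idx` signature genes.
oracle_overlap_p <- function(N, sig_idx, group_size, observed) {
  combos <- utils::combn(N, group_size)
  hits <- colSums(matrix(combos %in% sig_idx, nrow = group_size))
  mean(hits >= observed)
}

# Benjamini-Hochberg step-up computed literally from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

# Maximum pairwise distance over all point pairs, O(n^2).
oracle_feret <- function(points) {
  p <- as.matrix(points)
  max(stats::dist(p))
}

# Point-to-polyline distance by numeric optimisation over each segment's
# parameter, independent of the package's closed-form projection.
oracle_polyline_distance <- function(px, py, path) {
  p <- as.matrix(path)
  best <- Inf
  for (i in seq_len(nrow(p) - 1)) {
    f <- function(t) {
      qx <- p[i, 1] + t * (p[i + 1, 1] - p[i, 1])
      qy <- p[i, 2] + t * (p[i + 1, 2] - p[i, 2])
      sqrt((px - qx)^2 + (py - qy)^2)
    }
    best <- min(best, stats::optimize(f, c(0, 1), tol = 1e-12)$objective,
                f(0), f(1))
  }
  best
}

# Densified polyline: points every `step` along each segment.
densify_path <- function(path, step = 0.005) {
  p <- as.matrix(path)
  out <- NULL
  for (i in seq_len(nrow(p) - 1)) {
    len <- sqrt(sum((p[i + 1, ] - p[i, ])^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len / step)))
    out <- rbind(out, cbind(p[i, 1] + t * (p[i + 1, 1] - p[i, 1]),
                            p[i, 2] + t * (p[i + 1, 2] - p[i, 2])))
  }
  out
}

# A tiny deterministic counts tibble: two conditions, boundary-ready.
make_counts <- function(m, conditions) {
  colnames(m) <- conditions
  dplyr::bind_cols(
    tibble::tibble(gene = sprintf("G%02d", seq_len(nrow(m)))),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}
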
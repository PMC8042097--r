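# Internal helpers shared across modules.

# Fixed per-generator offsets expand one global seed into independent
# substreams, so adding a generator never perturbs another's draws.
.seed_offsets <- c(atlas = 101L, counts = 211L, axons = 307L, cells = 401L)

substream_seed <- function(seed, generator) {
  stopifnot(generator %in% names(.seed_offsets))
  as.integer((as.numeric(seed) + .seed_offsets[[generator]]) %% (2^31 - 1))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Sample headers follow the `condition:replicate` dialect used by all TSV
# matrices in the package; a header without ':' (e.g. a condition-averaged
# atlas column) is its own condition with a single implicit replicate.
parse_sample_labels <- function(samples) {
  parts <- stringr::str_split_fixed(samples, ":", 2)
  no_rep <- parts[, 2] == ""
  parts[no_rep, 1] <- samples[no_rep]
  parts[no_rep, 2] <- "1"
  tibble::tibble(
    sample = samples,
    condition = parts[, 1],
    replicate = parts[, 2]
  )
}

# condition-averaged matrix (robust to single-gene and single-condition input)
condition_means <- function(m, info) {
  conds <- unique(info$condition)
  cm <- vapply(conds, function(cc) {
    rowMeans(m[, info$sample[info$condition == cc], drop = FALSE])
  }, numeric(nrow(m)))
  if (!is.matrix(cm)) {
    cm <- matrix(cm, nrow = nrow(m), dimnames = list(rownames(m), conds))
  }
  cm
}

sample_columns <- function(tbl) setdiff(names(tbl), "gene")

# gene x sample tibble -> numeric matrix with gene rownames
as_expr_matrix <- function(tbl) {
  m <- as.matrix(tbl[sample_columns(tbl)])
  rownames(m) <- tbl$gene
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(m)),
    tibble::as_tibble(m)
  )
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number %s %s", name,
      if (strict) ">" else ">=", format(lower)
    ))
  }
  invisible(x)
}
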
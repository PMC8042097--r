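#' Read or write a gene-by-sample matrix as TSV
#'
#' Matrices are stored with genes as rows; the first column (`gene`) holds
#' gene identifiers and the remaining column headers follow the
#' `condition:replicate` convention (for example `CC:1` or `Oligodendrocyte:2`).
#' Duplicate gene identifiers are preserved on read (collapsing duplicates is
#' the job of [preprocess_atlas()]); duplicate sample headers are an error.
#'
#' @param path file path.
#' @param x a gene-by-sample tibble, as produced by the simulators.
#' @return `read_expression_tsv()` returns a tibble with a `gene` column and
#'   one numeric column per sample; `write_expression_tsv()` returns `path`
#'   invisibly.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("empty matrix file: %s", path))
  tbl <- readr::read_tsv(
    path,
    show_col_types = FALSE, progress = FALSE,
    name_repair = "minimal"
  )
  if (nrow(tbl) == 0 || ncol(tbl) < 2) {
    abort(sprintf("matrix file %s has no sample columns or no rows", path))
  }
  nm <- names(tbl)
  if (anyDuplicated(nm[-1])) {
    abort(sprintf(
      "duplicate sample headers in %s: %s", path,
      paste(unique(nm[-1][duplicated(nm[-1])]), collapse = ", ")
    ))
  }
  names(tbl)[1] <- "gene"
  bad <- !vapply(tbl[-1], is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf(
      "non-numeric sample columns in %s (ragged or malformed rows?): %s",
      path, paste(names(tbl)[-1][bad], collapse = ", ")
    ))
  }
  tbl$gene <- as.character(tbl$gene)
  tbl
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(is.data.frame(x), names(x)[1] == "gene")
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read and write gene-signature sets in GMT format
#'
#' One signature per line: name, description and then the member genes,
#' tab-separated. [write_gmt()] writes `.` for missing descriptions;
#' `write_gmt(read_gmt(path))` is the identity on names and gene lists.
#'
#' @param path GMT file path.
#' @param signatures a `wm_signatures` object or a named list of character
#'   vectors.
#' @return `read_gmt()` returns a [wm_signatures] object; `write_gmt()`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(new_wm_signatures(list()))
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d in %s (need name, description, >=1 gene)",
                  bad[1], path))
  }
  nms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate signature name in %s: %s", path,
                  nms[duplicated(nms)][1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  new_wm_signatures(sets)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(signatures, path) {
  sets <- as_signature_list(signatures)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, ".", sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
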
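# CSV dialects: header row = assay/descriptor names, first column = compound
# identifier, empty cell = missing (AC50 tables only).

read_table_checked <- function(path, allow_missing, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), na = "", progress = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    p <- prob[1, ]
    stop(sprintf("malformed cell in %s at row %d, column %d: expected %s",
                 path, p$row, p$col, p$expected), call. = FALSE)
  }
  if (ncol(tbl) < 2) stop(sprintf("%s needs an identifier column plus data columns", what),
                          call. = FALSE)
  ids <- tbl[[1]]
  if (anyNA(ids)) stop(sprintf("%s has missing compound identifiers", what), call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate compound identifier(s) in %s: %s", what,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (!allow_missing) {
    for (j in seq(2, ncol(tbl))) {
      bad <- which(is.na(tbl[[j]]))
      if (length(bad)) {
        stop(sprintf("missing value in %s at row %d, column '%s'",
                     what, bad[1], names(tbl)[j]), call. = FALSE)
      }
    }
  }
  tbl
}

#' Read and write descriptor feature tables
#'
#' Feature CSVs carry a compound identifier first column and numeric
#' descriptor columns; fingerprint columns (named in `fingerprint_cols`, or
#' autodetected by the `fp_` prefix) are validated as strictly binary.
#' Duplicate identifiers and malformed cells are rejected with their
#' coordinates.
#'
#' @param path CSV file path.
#' @param fingerprint_cols Columns to validate as binary; `NULL` autodetects
#'   names starting with `fp_`.
#' @return A tibble.
#' @export
read_feature_csv <- function(path, fingerprint_cols = NULL) {
  tbl <- read_table_checked(path, allow_missing = FALSE, what = "feature table")
  fp_cols <- fingerprint_cols %||% grep("^fp_", names(tbl), value = TRUE)
  for (cn in intersect(fp_cols, names(tbl))) {
    bad <- which(!tbl[[cn]] %in% c(0, 1))
    if (length(bad)) {
      stop(sprintf("fingerprint column '%s' has non-binary value %g at row %d",
                   cn, tbl[[cn]][bad[1]], bad[1]), call. = FALSE)
    }
  }
  tbl
}

#' @rdname read_feature_csv
#' @param x Table to write (identifier first column).
#' @export
write_feature_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}

#' Read and write AC50 assay matrices
#'
#' AC50 CSVs use an empty cell for a missing measurement; values must be
#' positive where present (the 1,000,000 sentinel marks inactives).
#'
#' @param path CSV file path.
#' @return A tibble with `NA` marking missing cells.
#' @export
read_ac50_csv <- function(path) {
  tbl <- read_table_checked(path, allow_missing = TRUE, what = "AC50 table")
  for (j in seq(2, ncol(tbl))) {
    bad <- which(!is.na(tbl[[j]]) & tbl[[j]] <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive AC50 at row %d, column '%s'",
                   bad[1], names(tbl)[j]), call. = FALSE)
    }
  }
  tbl
}

#' @rdname read_ac50_csv
#' @param x Table to write.
#' @export
write_ac50_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}

#' Read and write a run configuration
#'
#' A run configuration is a named list (paths, methods, seeds, repeats,
#' augmentation flag, module defaults) serialized as YAML; the round-trip is
#' lossless for scalars, vectors and nested lists.
#'
#' @param config Named list.
#' @param path YAML file path.
#' @return `read_run_config()` returns the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
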
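#' Binarize AC50 activity values
#'
#' An AC50 is the concentration producing half-maximal assay activity;
#' inactive compounds carry the sentinel value 1,000,000. The binary
#' activity is 0 for the sentinel (inactive) and 1 otherwise. The sentinel
#' comparison uses a relative tolerance so values that went through a CSV
#' round-trip still binarize correctly.
#'
#' @param ac50 Numeric vector or matrix of positive AC50 values; missing
#'   entries are not permitted — extract a complete submatrix first.
#' @param sentinel Inactive sentinel value (default 1e6).
#' @param rel_tol Relative tolerance of the sentinel comparison.
#' @return Integer labels with the same shape as `ac50`.
#' @examples
#' binarize_activity(c(1e6, 0.5, 1e6))  # 0 1 0
#' @export
binarize_activity <- function(ac50, sentinel = 1e6, rel_tol = 1e-9) {
  if (is.data.frame(ac50)) ac50 <- as.matrix(ac50)
  if (anyNA(ac50)) {
    stop("missing AC50 values; run extract_complete_submatrix() first",
         call. = FALSE)
  }
  if (any(ac50 <= 0)) stop("AC50 values must be positive", call. = FALSE)
  lab <- ifelse(ac50 >= sentinel * (1 - rel_tol), 0L, 1L)
  if (is.matrix(ac50)) {
    lab <- matrix(as.integer(lab), nrow(ac50), dimnames = dimnames(ac50))
  } else {
    lab <- as.integer(lab)
  }
  lab
}

#' Extract a large complete submatrix from an incomplete assay matrix
#'
#' Finding the largest complete submatrix is NP-hard; this uses a greedy
#' heuristic that repeatedly deletes the row or column carrying the most
#' missingness until no missing entries remain. Rows and columns are
#' compared by missing fraction; ties go to the larger absolute missing
#' count, then columns before rows, then the lowest index.
#'
#' @param data A data frame whose first column is the compound identifier and
#'   remaining columns are assays (`NA` = missing), or a plain matrix.
#' @return The completed table in the same form, with a `deletion_log`
#'   attribute — a tibble of the deletions in order (`step`, `what`, `name`,
#'   `n_missing`, `frac_missing`). Retrieve it with [deletion_log()].
#' @export
extract_complete_submatrix <- function(data) {
  is_df <- is.data.frame(data)
  if (is_df) {
    ids <- data[[1]]
    m <- as.matrix(data[, -1, drop = FALSE])
    rownames(m) <- as.character(ids)
    id_name <- names(data)[1]
  } else {
    m <- as.matrix(data)
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  }
  log <- list()
  step <- 0L
  while (nrow(m) > 0 && ncol(m) > 0 && anyNA(m)) {
    row_miss <- rowSums(is.na(m))
    col_miss <- colSums(is.na(m))
    cand <- rbind(
      data.frame(what = "column", index = seq_len(ncol(m)),
                 name = colnames(m), n_missing = as.integer(col_miss),
                 frac = col_miss / nrow(m), stringsAsFactors = FALSE),
      data.frame(what = "row", index = seq_len(nrow(m)),
                 name = rownames(m), n_missing = as.integer(row_miss),
                 frac = row_miss / ncol(m), stringsAsFactors = FALSE)
    )
    cand <- cand[cand$n_missing > 0, ]
    # max fraction; ties -> larger count -> column before row -> lowest index
    ord <- order(-cand$frac, -cand$n_missing,
                 match(cand$what, c("column", "row")), cand$index)
    pick <- cand[ord[1], ]
    step <- step + 1L
    log[[step]] <- tibble::tibble(step = step, what = pick$what,
                                  name = pick$name,
                                  n_missing = pick$n_missing,
                                  frac_missing = pick$frac)
    if (pick$what == "column") {
      m <- m[, -pick$index, drop = FALSE]
    } else {
      m <- m[-pick$index, , drop = FALSE]
    }
  }
  if (nrow(m) == 0 || ncol(m) == 0) {
    warning("complete-submatrix extraction removed everything", call. = FALSE)
  }
  log_tbl <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(step = integer(), what = character(), name = character(),
                   n_missing = integer(), frac_missing = numeric())
  out <- if (is_df) {
    res <- tibble::as_tibble(as.data.frame(m))
    res <- tibble::add_column(res, !!id_name := rownames(m), .before = 1)
    res
  } else {
    m
  }
  attr(out, "deletion_log") <- log_tbl
  out
}

#' @rdname extract_complete_submatrix
#' @param x An object returned by [extract_complete_submatrix()].
#' @export
deletion_log <- function(x) attr(x, "deletion_log")

# Shared prevalence filter: keep columns whose positive fraction >= min_frac.
prevalence_filter <- function(m, min_frac, what) {
  if (is.data.frame(m)) {
    first_chr <- is.character(m[[1]]) || is.factor(m[[1]])
    if (first_chr) m <- m[, -1, drop = FALSE]
    m <- as.matrix(m)
  }
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0) {
    stop(sprintf("empty %s matrix", what), call. = FALSE)
  }
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop(sprintf("%s matrix must be binary with no missing entries", what),
         call. = FALSE)
  }
  frac <- colSums(m) / nrow(m)
  keep <- frac >= min_frac
  nms <- colnames(m)
  retained <- if (is.null(nms)) which(keep) else nms[keep]
  attr(retained, "prevalence") <- setNames(frac, nms)
  retained
}

#' Drop assays with too few active compounds
#'
#' An assay is kept only when at least `min_frac` of the compounds are
#' active in it; assays with strictly less than that fraction of actives are
#' removed (default 5%).
#'
#' @param labels Binary compounds-by-assays matrix or data frame (an
#'   identifier first column is ignored).
#' @param min_frac Minimum active fraction to keep an assay.
#' @return The retained assay names (or indices when unnamed), with the
#'   per-assay active fractions in attribute `prevalence`.
#' @export
filter_low_active_assays <- function(labels, min_frac = 0.05) {
  prevalence_filter(labels, min_frac, "assay label")
}

#' Drop rare fingerprints
#'
#' A fingerprint present in strictly less than `min_frac` of the compounds
#' (default 5%) is removed.
#'
#' @param fp Binary compounds-by-fingerprints matrix or data frame.
#' @param min_frac Minimum prevalence to keep a fingerprint.
#' @return Retained fingerprint names/indices with attribute `prevalence`.
#' @export
filter_rare_fingerprints <- function(fp, min_frac = 0.05) {
  prevalence_filter(fp, min_frac, "fingerprint")
}

#' Min-max normalization of continuous descriptors
#'
#' Scales every column into `[0, 1]` by its observed minimum and maximum;
#' constant columns map to 0. The scaling statistics are attached so they
#' can be re-applied — fit on a whole dataset (the default usage) or on a
#' training partition only, then applied to held-out data via `stats`.
#'
#' @param x Data frame or matrix of finite continuous descriptors (an
#'   identifier first column is carried through untouched).
#' @param stats Optional scaling statistics from a previous call (tibble
#'   with `column`, `min`, `max`); when supplied they are applied instead of
#'   being re-estimated. Out-of-range values are clipped to `[0, 1]`.
#' @return A tibble of scaled descriptors with attribute `scaling`.
#' @export
normalize_physchem <- function(x, stats = NULL) {
  id <- NULL
  id_name <- NULL
  if (is.data.frame(x) && (is.character(x[[1]]) || is.factor(x[[1]]))) {
    id <- x[[1]]
    id_name <- names(x)[1]
    x <- x[, -1, drop = FALSE]
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- sprintf("V%d", seq_len(ncol(m)))
  bad <- colnames(m)[!apply(m, 2, function(v) all(is.finite(v)))]
  if (length(bad)) {
    stop(sprintf("non-finite values in column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.null(stats)) {
    stats <- tibble::tibble(column = colnames(m),
                            min = apply(m, 2, min),
                            max = apply(m, 2, max))
  } else {
    stats <- tibble::as_tibble(stats)
    miss <- setdiff(colnames(m), stats$column)
    if (length(miss)) {
      stop(sprintf("no scaling statistics for column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    stats <- stats[match(colnames(m), stats$column), ]
  }
  rng <- stats$max - stats$min
  scaled <- sweep(m, 2, stats$min, "-")
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  scaled <- pmin(pmax(scaled, 0), 1)
  out <- tibble::as_tibble(as.data.frame(scaled))
  if (!is.null(id)) out <- tibble::add_column(out, !!id_name := id, .before = 1)
  attr(out, "scaling") <- stats
  out
}

#' @rdname normalize_physchem
#' @export
scaling_stats <- function(x) attr(x, "scaling")

#' Full assay-matrix curation pipeline
#'
#' Runs the dataset-construction pipeline in its fixed order: extract a
#' complete AC50 submatrix, binarize activity against the 1,000,000
#' sentinel, drop assays with fewer than `min_active_frac` actives, drop
#' fingerprints present in fewer than `min_fp_frac` compounds, and min-max
#' normalize the continuous descriptors. Compounds are aligned across the
#' three tables by their identifier column.
#'
#' @param ac50 AC50 table: first column compound identifier, one column per
#'   assay, `NA` = missing.
#' @param physchem Continuous descriptor table (first column identifier).
#' @param fingerprints Binary fingerprint table (first column identifier).
#' @param min_active_frac,min_fp_frac Prevalence thresholds (default 5%).
#' @return A list of class `gnetox_dataset`: `features` (tibble: identifier,
#'   normalized physchem block, fingerprint block), `labels` (tibble:
#'   identifier + one binary column per retained assay), `physchem_cols`,
#'   `fingerprint_cols`, and `log` (deletion log, retained assay /
#'   fingerprint sets, scaling statistics, pipeline order).
#' @export
curate <- function(ac50, physchem, fingerprints,
                   min_active_frac = 0.05, min_fp_frac = 0.05) {
  stopifnot(is.data.frame(ac50), is.data.frame(physchem),
            is.data.frame(fingerprints))
  complete <- extract_complete_submatrix(ac50)
  ids <- complete[[1]]
  ids <- intersect(ids, intersect(physchem[[1]], fingerprints[[1]]))
  if (length(ids) == 0) stop("no compounds shared by all three tables", call. = FALSE)
  complete <- complete[match(ids, complete[[1]]), ]
  pc <- physchem[match(ids, physchem[[1]]), ]
  fp <- fingerprints[match(ids, fingerprints[[1]]), ]

  lab_mat <- binarize_activity(as.matrix(complete[, -1, drop = FALSE]))
  kept_assays <- filter_low_active_assays(lab_mat, min_active_frac)
  lab_mat <- lab_mat[, kept_assays, drop = FALSE]

  fp_mat <- as.matrix(fp[, -1, drop = FALSE])
  kept_fp <- filter_rare_fingerprints(fp_mat, min_fp_frac)
  fp_mat <- fp_mat[, kept_fp, drop = FALSE]

  pc_scaled <- normalize_physchem(pc)
  id_name <- names(ac50)[1]
  features <- dplyr::bind_cols(
    pc_scaled,
    tibble::as_tibble(as.data.frame(fp_mat))
  )
  labels <- tibble::as_tibble(as.data.frame(lab_mat))
  labels <- tibble::add_column(labels, !!id_name := ids, .before = 1)
  structure(
    list(features = features,
         labels = labels,
         physchem_cols = setdiff(names(pc_scaled), id_name),
         fingerprint_cols = colnames(fp_mat),
         log = list(order = c("complete_submatrix", "binarize",
                              "assay_filter", "fingerprint_filter",
                              "normalize"),
                    deletions = deletion_log(complete),
                    retained_assays = as.character(kept_assays),
                    retained_fingerprints = as.character(kept_fp),
                    scaling = scaling_stats(pc_scaled))),
    class = "gnetox_dataset"
  )
}

#' @export
print.gnetox_dataset <- function(x, ...) {
  cat(sprintf("<gnetox_dataset> %d compounds x (%d physchem + %d fingerprints), %d assay(s)\n",
              nrow(x$features), length(x$physchem_cols),
              length(x$fingerprint_cols), ncol(x$labels) - 1L))
  invisible(x)
}

#' @method glance gnetox_dataset
#' @export
glance.gnetox_dataset <- function(x, ...) {
  lab <- as.matrix(x$labels[, -1, drop = FALSE])
  tibble::tibble(n_compounds = nrow(x$features),
                 n_physchem = length(x$physchem_cols),
                 n_fingerprints = length(x$fingerprint_cols),
                 n_assays = ncol(lab),
                 mean_active_frac = mean(colMeans(lab)))
}
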
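#' SMOTE minority oversampling
#'
#' Balances a binary training set by synthesizing minority-class samples:
#' each synthetic point is `p + u * (n - p)` for a random minority point `p`,
#' a random one of its `k` nearest minority neighbors `n` (Euclidean distance
#' on the full feature vector, ties broken by row index), and
#' `u ~ uniform[0, 1]`. Original rows are preserved and kept first; synthetic
#' rows are appended until the minority:majority ratio reaches `ratio`
#' exactly (rounding the majority target up). Fractional values on binary
#' fingerprint columns are deliberately kept un-rounded, so the augmented
#' cloud is continuous.
#'
#' Only training partitions should ever be augmented; the benchmark harness
#' guarantees test partitions are untouched.
#'
#' @param x Feature data frame or matrix (numeric columns).
#' @param y Binary labels (0/1), both classes present, minority count >= 2.
#' @param k Number of nearest minority neighbors (default 5); reduced with a
#'   warning when the minority class has at most `k` members.
#' @param ratio Target minority:majority ratio after augmentation
#'   (default 1, i.e. fully balanced).
#' @param seed Integer seed; the augmentation is deterministic given it.
#' @return A list of class `smote_result`: `x` (tibble, originals first),
#'   `y`, `n_synthetic`, and `parents` — a tibble recording for every
#'   synthetic row the base row, neighbor row (indices into the original
#'   data) and interpolation weight `u`.
#' @export
smote_augment <- function(x, y, k = 5, ratio = 1, seed = 1) {
  xm <- as_feature_matrix(x, unit_interval = FALSE)
  y <- check_binary_labels(y)
  if (nrow(xm) != length(y)) stop("`x` and `y` sizes disagree", call. = FALSE)
  stopifnot(k >= 1, ratio > 0)
  counts <- table(factor(y, levels = c(0, 1)))
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min < 2) stop("minority class needs at least 2 samples", call. = FALSE)
  needed <- as.integer(ceiling(n_maj * ratio) - n_min)
  out_x <- tibble::as_tibble(as.data.frame(xm))
  if (needed <= 0) {
    return(structure(list(x = out_x, y = y, n_synthetic = 0L,
                          parents = tibble::tibble(base = integer(),
                                                   neighbor = integer(),
                                                   u = numeric())),
                     class = "smote_result"))
  }
  min_idx <- which(y == minority)
  if (k >= n_min) {
    warning(sprintf("k reduced from %d to %d (minority class has %d samples)",
                    k, n_min - 1L, n_min), call. = FALSE)
    k <- n_min - 1L
  }
  d <- as.matrix(dist(xm[min_idx, , drop = FALSE]))
  # k nearest minority neighbors per minority point, ties by row index
  nn <- lapply(seq_len(n_min), function(i) {
    ord <- order(d[i, ], seq_len(n_min))
    ord <- ord[ord != i]
    min_idx[ord[seq_len(k)]]
  })
  synth <- with_seed_(seed, {
    base_local <- sample.int(n_min, needed, replace = TRUE)
    nb_pick <- sample.int(k, needed, replace = TRUE)
    u <- runif(needed)
    base <- min_idx[base_local]
    neighbor <- vapply(seq_len(needed),
                       function(s) nn[[base_local[s]]][nb_pick[s]], integer(1))
    rows <- xm[base, , drop = FALSE] +
      u * (xm[neighbor, , drop = FALSE] - xm[base, , drop = FALSE])
    list(rows = rows, base = base, neighbor = neighbor, u = u)
  })
  x_aug <- rbind(xm, synth$rows)
  rownames(x_aug) <- NULL
  structure(
    list(x = tibble::as_tibble(as.data.frame(x_aug)),
         y = c(y, rep(minority, needed)),
         n_synthetic = needed,
         parents = tibble::tibble(base = synth$base,
                                  neighbor = synth$neighbor, u = synth$u)),
    class = "smote_result"
  )
}

#' @export
print.smote_result <- function(x, ...) {
  cat(sprintf("<smote_result> %d original + %d synthetic rows (classes: %s)\n",
              nrow(x$x) - x$n_synthetic, x$n_synthetic,
              paste(sprintf("%s=%d", names(table(x$y)), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}

#' @method tidy smote_result
#' @export
tidy.smote_result <- function(x, ...) {
  n_orig <- nrow(x$x) - x$n_synthetic
  dplyr::mutate(x$x,
                label = x$y,
                origin = rep(c("original", "synthetic"),
                             c(n_orig, x$n_synthetic)))
}

#' Scatter of two descriptors before/after augmentation
#'
#' @param object A [smote_augment()] result.
#' @param cols Two column names or indices to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot smote_result
#' @export
autoplot.smote_result <- function(object, cols = c(1, 2), ...) {
  df <- tidy(object)
  nm <- names(object$x)[if (is.numeric(cols)) cols else match(cols, names(object$x))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                   colour = factor(.data$label),
                                   shape = .data$origin)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "class", shape = NULL) +
    ggplot2::theme_minimal()
}
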
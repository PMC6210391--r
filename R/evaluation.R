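#' Repeated random train/test splits
#'
#' Creates `r_splits` independent random partitions of `1:n` into a training
#' set and its complementary test set. With `stratify` labels, the test-set
#' quota is allocated to the classes by largest remainder so every partition
#' receives at least one sample per class on each side and the test size is
#' `round(n * test_frac)` in every instance.
#'
#' @param n Number of samples (>= 4).
#' @param r_splits Number of split instances (default 50).
#' @param test_frac Test fraction (default 0.25).
#' @param seed Integer seed; the split set is reproducible given it.
#' @param stratify Optional binary labels to stratify on.
#' @return An object of class `split_set`: `splits` is a list of
#'   `list(train, test)` index pairs.
#' @export
make_splits <- function(n, r_splits = 50, test_frac = 0.25, seed = 1,
                        stratify = NULL) {
  stopifnot(n >= 4, r_splits >= 1, test_frac > 0, test_frac < 1)
  m_test <- round(n * test_frac)
  m_test <- min(max(m_test, 1L), n - 1L)
  if (!is.null(stratify)) {
    yl <- check_binary_labels(stratify, require_both = TRUE)
    if (length(yl) != n) stop("`stratify` must have length `n`", call. = FALSE)
    cls_n <- table(factor(yl, levels = c(0, 1)))
    if (min(cls_n) < 2) {
      stop("stratified split infeasible: a class has fewer than 2 samples",
           call. = FALSE)
    }
    # largest-remainder allocation of the test quota across the two classes
    raw <- as.numeric(cls_n) * test_frac
    base <- floor(raw)
    left <- m_test - sum(base)
    if (left > 0) {
      add <- order(-(raw - base))[seq_len(left)]
      base[add] <- base[add] + 1
    } else if (left < 0) {
      sub <- order(raw - base)[seq_len(-left)]
      base[sub] <- base[sub] - 1
    }
    # every class keeps >= 1 sample on both sides
    base <- pmax(pmin(base, as.numeric(cls_n) - 1), 1)
    quota <- setNames(as.integer(base), c("0", "1"))
  }
  splits <- with_seed_(seed, {
    lapply(seq_len(r_splits), function(r) {
      if (is.null(stratify)) {
        test <- sort(sample.int(n, m_test))
      } else {
        test <- sort(unlist(lapply(c(0L, 1L), function(cl) {
          idx <- which(yl == cl)
          sample(idx, quota[as.character(cl)])
        }), use.names = FALSE))
      }
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
  structure(list(splits = splits, n = n, r_splits = r_splits,
                 test_frac = test_frac, seed = seed,
                 stratified = !is.null(stratify)),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set> %d instance(s) of n=%d (test fraction %.2f%s)\n",
              x$r_splits, x$n, x$test_frac,
              if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' @method tidy split_set
#' @export
tidy.split_set <- function(x, ...) {
  purrr::map_dfr(seq_along(x$splits), function(r) {
    s <- x$splits[[r]]
    tibble::tibble(split = r,
                   role = rep(c("train", "test"),
                              c(length(s$train), length(s$test))),
                   index = c(s$train, s$test))
  })
}

#' Confusion counts and classification metrics
#'
#' Counts true/false positives and negatives by exhaustive comparison and
#' reports `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`
#' and balanced accuracy `BA = (sensitivity + specificity) / 2`. A metric
#' whose denominator is empty (e.g. no positives in the test set) is
#' reported as `NA` and must be excluded from aggregation, never treated as
#' zero.
#'
#' @param y_true,y_pred Equal-length binary vectors, non-empty.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ba`.
#' @examples
#' # TP=3, FN=1, TN=5, FP=5 -> sens 0.75, spec 0.5, BA 0.625
#' compute_metrics(rep(c(1, 0), c(4, 10)), c(1, 1, 1, 0, rep(1, 5), rep(0, 5)))
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- check_binary_labels(y_true, require_both = FALSE, arg = "y_true")
  y_pred <- check_binary_labels(y_pred, require_both = FALSE, arg = "y_pred")
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` lengths differ", call. = FALSE)
  }
  if (length(y_true) == 0) stop("empty label vectors", call. = FALSE)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ba <- (sens + spec) / 2
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, ba = ba)
}

# ---- method adapters --------------------------------------------------------

# Each adapter: fit on (x_train, y_train), return predicted labels on x_test.
benchmark_methods <- function() {
  list(
    rnn = function(xtr, ytr, xte, cfg, seed) {
      fit <- train_rnn(xtr, ytr, hidden = cfg$rnn_hidden, lr = cfg$rnn_lr,
                       epochs = cfg$rnn_epochs, seed = seed)
      suppressWarnings(predict(fit, xte))$label
    },
    mlrnn = function(xtr, ytr, xte, cfg, seed) {
      fit <- train_mlrnn(xtr, ytr, ridge = cfg$mlrnn_ridge,
                         folds = cfg$mlrnn_folds, seed = seed,
                         n_models = cfg$mlrnn_models)
      predict(fit, xte)$label
    },
    xgboost = function(xtr, ytr, xte, cfg, seed) {
      dtr <- xgboost::xgb.DMatrix(xtr, label = ytr, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = cfg$xgb_max_depth, eta = cfg$xgb_eta,
                      nthread = 1, seed = seed),
        data = dtr, nrounds = cfg$xgb_nrounds
      )
      p <- predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1))
      as.integer(p >= 0.5)
    },
    majority = function(xtr, ytr, xte, cfg, seed) {
      maj <- as.integer(mean(ytr) >= 0.5)
      rep(maj, nrow(xte))
    }
  )
}

# Defaults for the adapters; xgboost values are the wrapped library's usual
# settings and are recorded verbatim in the benchmark config attribute.
default_benchmark_config <- function() {
  list(rnn_hidden = 4, rnn_lr = 0.1, rnn_epochs = 30,
       mlrnn_ridge = 10^seq(-2, 2), mlrnn_folds = 3, mlrnn_models = 1,
       xgb_nrounds = 50, xgb_max_depth = 3, xgb_eta = 0.3,
       smote_k = 5, smote_ratio = 1)
}

#' Repeated-split benchmark over assays and methods
#'
#' For every assay, builds a stratified [make_splits()] set, then for every
#' split and method trains on the training partition (optionally
#' SMOTE-augmented) and predicts on the untouched test partition, recording
#' confusion counts and sensitivity / specificity / balanced accuracy. The
#' split sets depend only on `seed`, so an unbalanced run and an augmented
#' run with the same seed are evaluated on byte-identical test partitions —
#' the paired-comparison contract.
#'
#' @param data A `gnetox_dataset` (from [curate()] or
#'   [generate_assay_data()]), or a feature data frame when `labels` is
#'   given.
#' @param labels Optional data frame of per-assay binary labels (identifier
#'   first column, one column per assay) when `data` is a plain feature
#'   table.
#' @param methods Subset of `c("rnn", "mlrnn", "xgboost", "majority")`.
#' @param r_splits Number of split instances per assay.
#' @param test_frac Test fraction.
#' @param seed Master seed; per-cell seeds are derived as
#'   `seed + 1009 * assay_index + split_index`.
#' @param augment If `TRUE`, SMOTE-augment each training partition to a
#'   balanced class ratio before fitting (test partitions untouched).
#' @param config Named list overriding [default_benchmark_config()] entries.
#' @return A tibble of class `gnetox_benchmark` with one row per
#'   assay x split x method: condition, confusion counts, metrics and a
#'   `failed` flag (a failed fit is recorded and skipped by aggregation,
#'   never silently averaged). Attributes: `splits` (per-assay
#'   `split_set`s), `config`.
#' @export
run_benchmark <- function(data, labels = NULL,
                          methods = c("rnn", "mlrnn", "xgboost"),
                          r_splits = 10, test_frac = 0.25, seed = 1,
                          augment = FALSE, config = list()) {
  if (inherits(data, "gnetox_dataset")) {
    features <- data$features
    labels <- data$labels
  } else {
    features <- data
    if (is.null(labels)) stop("`labels` required when `data` is a plain table",
                              call. = FALSE)
  }
  x <- as_feature_matrix(features)
  lab <- labels
  if (is.character(lab[[1]]) || is.factor(lab[[1]])) lab <- lab[, -1, drop = FALSE]
  assays <- names(lab)
  registry <- benchmark_methods()
  unknown <- setdiff(methods, names(registry))
  if (length(unknown)) {
    stop(sprintf("no adapter for method(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (length(methods) == 0) stop("`methods` must be non-empty", call. = FALSE)
  cfg <- modifyList(default_benchmark_config(), config)
  condition <- if (augment) "augmented" else "unbalanced"

  split_sets <- list()
  rows <- list()
  for (ai in seq_along(assays)) {
    a <- assays[ai]
    y <- check_binary_labels(lab[[a]], require_both = FALSE, arg = a)
    if (length(unique(y)) < 2 || min(table(y)) < 2) {
      stop(sprintf("stratification infeasible for assay '%s': too few samples in a class", a),
           call. = FALSE)
    }
    ss <- make_splits(nrow(x), r_splits = r_splits, test_frac = test_frac,
                      seed = seed + 1009L * ai, stratify = y)
    split_sets[[a]] <- ss
    for (r in seq_len(r_splits)) {
      s <- ss$splits[[r]]
      cell_seed <- seed + 1009L * ai + r
      xtr <- x[s$train, , drop = FALSE]
      ytr <- y[s$train]
      if (augment) {
        aug <- smote_augment(xtr, ytr, k = cfg$smote_k,
                             ratio = cfg$smote_ratio, seed = cell_seed)
        xtr <- as.matrix(aug$x)
        ytr <- aug$y
      }
      xte <- x[s$test, , drop = FALSE]
      yte <- y[s$test]
      for (mth in methods) {
        pred <- tryCatch(registry[[mth]](xtr, ytr, xte, cfg, cell_seed),
                         error = function(e) e)
        if (inherits(pred, "error")) {
          warning(sprintf("assay %s split %d method %s failed: %s",
                          a, r, mth, conditionMessage(pred)), call. = FALSE)
          m <- tibble::tibble(tp = NA_integer_, fp = NA_integer_,
                              tn = NA_integer_, fn = NA_integer_,
                              sensitivity = NA_real_, specificity = NA_real_,
                              ba = NA_real_)
          failed <- TRUE
        } else {
          m <- compute_metrics(yte, pred)
          failed <- FALSE
        }
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(assay = a, split = r, method = mth,
                         condition = condition),
          m, tibble::tibble(failed = failed))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "splits") <- split_sets
  attr(out, "config") <- cfg
  class(out) <- c("gnetox_benchmark", class(out))
  out
}

#' Run the paired unbalanced vs SMOTE-augmented benchmark
#'
#' Convenience wrapper running [run_benchmark()] twice with the same seed —
#' once on the raw unbalanced training sets and once with SMOTE-balanced
#' training sets — so both conditions share identical test partitions.
#'
#' @inheritParams run_benchmark
#' @return A `gnetox_benchmark` tibble with both conditions stacked;
#'   attributes `splits_unbalanced` / `splits_augmented` carry the per-assay
#'   split sets of each run.
#' @export
compare_augmentation <- function(data, labels = NULL,
                                 methods = c("rnn", "mlrnn", "xgboost"),
                                 r_splits = 10, test_frac = 0.25, seed = 1,
                                 config = list()) {
  raw <- run_benchmark(data, labels, methods = methods, r_splits = r_splits,
                       test_frac = test_frac, seed = seed, augment = FALSE,
                       config = config)
  aug <- run_benchmark(data, labels, methods = methods, r_splits = r_splits,
                       test_frac = test_frac, seed = seed, augment = TRUE,
                       config = config)
  out <- dplyr::bind_rows(raw, aug)
  attr(out, "splits_unbalanced") <- attr(raw, "splits")
  attr(out, "splits_augmented") <- attr(aug, "splits")
  attr(out, "config") <- attr(raw, "config")
  class(out) <- c("gnetox_benchmark", class(out))
  out
}

#' Aggregate a benchmark: means and spreads over splits
#'
#' Unweighted means and standard deviations over split instances, grouped by
#' the requested keys. Failed cells and undefined metrics (`NA`) are
#' excluded, and the number of exclusions is reported per group.
#'
#' @param bench A [run_benchmark()] result.
#' @param by Grouping columns (default method x condition x assay).
#' @return A tibble of aggregated metrics.
#' @export
summarise_benchmark <- function(bench,
                                by = c("method", "condition", "assay")) {
  stopifnot(all(by %in% names(bench)))
  bench |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_excluded = sum(.data$failed | is.na(.data$ba)),
      ba_sd = sd(.data$ba[!.data$failed], na.rm = TRUE),
      sensitivity = mean(.data$sensitivity[!.data$failed], na.rm = TRUE),
      specificity = mean(.data$specificity[!.data$failed], na.rm = TRUE),
      ba = mean(.data$ba[!.data$failed], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::relocate("ba_sd", .after = "ba")
}

#' Per-assay benchmark summary figure
#'
#' Mean test metrics per assay, colored by method, faceted by metric, with
#' line type distinguishing the unbalanced and augmented conditions.
#'
#' @param object A `gnetox_benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gnetox_benchmark
#' @export
autoplot.gnetox_benchmark <- function(object, ...) {
  summ <- summarise_benchmark(object)
  long <- tidyr::pivot_longer(summ, c("sensitivity", "specificity", "ba"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$assay, y = .data$value,
                                     colour = .data$method,
                                     linetype = .data$condition,
                                     group = interaction(.data$method,
                                                         .data$condition))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = "assay", y = "mean test value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
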
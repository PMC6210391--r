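#' Single-cell RNN transfer function
#'
#' The excitation probability of an isolated RNN cell receiving total
#' excitatory drive `x_plus` and inhibitory drive `x_minus` while firing at
#' rate `r`: `min(1, x_plus / (r + x_minus))`. Vectorized; drives are
#' recycled against each other.
#'
#' @param x_plus,x_minus Non-negative rates.
#' @param r Positive firing rate.
#' @return Excitation probabilities in `[0, 1]`.
#' @examples
#' activation_cell(0.3, 0, 1)  # 0.3
#' activation_cell(2, 0, 1)    # saturates at 1
#' @export
activation_cell <- function(x_plus, x_minus, r = 1) {
  if (any(r <= 0)) stop("firing rate `r` must be strictly positive", call. = FALSE)
  if (any(x_plus < 0) || any(x_minus < 0)) {
    stop("drives must be non-negative", call. = FALSE)
  }
  q <- x_plus / (r + x_minus)
  q[q > 1] <- 1
  q
}

#' Initialize a multi-layer RNN model
#'
#' The MLRNN maps `d` descriptors to a fixed set of 20 input rates through a
#' non-negative random projection (columns normalized to sum to one, so each
#' input rate is a weighted average of descriptors and stays in `[0, 1]`),
#' drives 100 hidden RNN cells through independent random excitatory and
#' inhibitory weight matrices, and reads the hidden excitation probabilities
#' out with a linear model fit by ridge least squares. All random structure
#' is fixed at initialization and fully determined by `seed`.
#'
#' @param d Number of descriptors (columns of the feature table).
#' @param seed Integer seed.
#' @param n_inputs Width of the projected input layer (default 20).
#' @param n_hidden Number of hidden RNN cells (default 100).
#' @param w_max Upper bound of the uniform hidden-weight initialization.
#' @param rate Firing rate of every hidden cell.
#' @return An object of class `mlrnn_model` with elements `projection`
#'   (`d x n_inputs`), `w_plus`, `w_minus` (`n_inputs x n_hidden`), `rate`,
#'   and `seed`.
#' @export
init_mlrnn <- function(d, seed = 1, n_inputs = 20, n_hidden = 100,
                       w_max = 1, rate = 1) {
  stopifnot(d >= 1, n_inputs >= 1, n_hidden >= 1, w_max > 0, rate > 0)
  with_seed_(seed, {
    projection <- matrix(runif(d * n_inputs), d, n_inputs)
    projection <- sweep(projection, 2, colSums(projection), "/")
    w_plus <- matrix(runif(n_inputs * n_hidden, 0, w_max), n_inputs, n_hidden)
    w_minus <- matrix(runif(n_inputs * n_hidden, 0, w_max), n_inputs, n_hidden)
    structure(list(projection = projection, w_plus = w_plus,
                   w_minus = w_minus, rate = rate, seed = seed,
                   d = d, n_inputs = n_inputs, n_hidden = n_hidden),
              class = "mlrnn_model")
  })
}

# Hidden-layer activations: n x n_hidden matrix of excitation probabilities.
mlrnn_hidden <- function(model, x) {
  u <- x %*% model$projection
  activation_cell(u %*% model$w_plus, u %*% model$w_minus, model$rate)
}

#' Ridge least-squares readout
#'
#' Solves `min ||H beta + b - y||^2 + ridge * ||beta||^2` (the bias `b` is
#' not penalized) through the regularized normal equations.
#'
#' @param h Hidden-activation matrix (`n x p`).
#' @param y Numeric response (binary labels for classification).
#' @param ridge Non-negative regularization strength. Must be positive when
#'   `h` is rank-deficient.
#' @return A list with `weights` (length `p`) and `bias`.
#' @export
fit_readout <- function(h, y, ridge = 0) {
  h <- as.matrix(h)
  y <- as.numeric(y)
  stopifnot(nrow(h) == length(y), ridge >= 0)
  p <- ncol(h)
  ha <- cbind(h, 1)
  pen <- diag(c(rep(1, p), 0))
  lhs <- crossprod(ha) + ridge * pen
  rhs <- crossprod(ha, y)
  beta <- tryCatch(
    solve(lhs, rhs),
    error = function(e) {
      stop("singular readout system; use ridge > 0", call. = FALSE)
    }
  )
  list(weights = as.numeric(beta[seq_len(p)]), bias = as.numeric(beta[p + 1]))
}

#' Train a multi-layer RNN classifier
#'
#' Fits [init_mlrnn()] models with a ridge least-squares readout on the
#' hidden excitation probabilities. The ridge strength is selected by
#' stratified cross-validation maximizing balanced accuracy, then `n_models`
#' independently seeded networks are fit with the selected ridge; prediction
#' averages the member scores (the trial-averaging ensemble).
#'
#' @inheritParams train_rnn
#' @param ridge Numeric grid of ridge strengths to cross-validate.
#' @param folds Stratified CV folds.
#' @param n_models Ensemble size (independently seeded members; default 1,
#'   use 20 for trial averaging).
#' @param ... Passed to [init_mlrnn()] (`n_inputs`, `n_hidden`, `w_max`,
#'   `rate`).
#' @return An object of class `mlrnn_fit`.
#' @export
train_mlrnn <- function(x, y, ridge = 10^seq(-3, 2), folds = 5, seed = 1,
                        n_models = 1, threshold = 0.5, ...) {
  x <- as_feature_matrix(x)
  y <- check_binary_labels(y)
  if (nrow(x) != length(y)) stop("`x` and `y` sizes disagree", call. = FALSE)
  stopifnot(length(ridge) >= 1, all(ridge >= 0), n_models >= 1)
  folds <- min(folds, min(table(y)))
  if (folds < 2) stop("`y` is too unbalanced for stratified cross-validation",
                      call. = FALSE)
  fold <- make_folds(y, folds, seed)
  cv_model <- init_mlrnn(ncol(x), seed = seed, ...)
  h_all <- mlrnn_hidden(cv_model, x)
  cv_ba <- vapply(ridge, function(lam) {
    bas <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      ro <- fit_readout(h_all[tr, , drop = FALSE], y[tr],
                        ridge = max(lam, 1e-10))
      score <- h_all[!tr, , drop = FALSE] %*% ro$weights + ro$bias
      compute_metrics(y[!tr], as.integer(score >= threshold))$ba
    }, numeric(1))
    mean(bas, na.rm = TRUE)
  }, numeric(1))
  best_ridge <- ridge[order(-cv_ba, ridge)[1]]
  members <- lapply(seq_len(n_models), function(m) {
    model <- init_mlrnn(ncol(x), seed = seed + m - 1L, ...)
    h <- mlrnn_hidden(model, x)
    list(model = model, readout = fit_readout(h, y, ridge = max(best_ridge, 1e-10)))
  })
  structure(
    list(members = members, ridge = best_ridge,
         cv = tibble::tibble(ridge = ridge, mean_val_ba = cv_ba),
         threshold = threshold, d = ncol(x), seed = seed,
         n_models = n_models),
    class = "mlrnn_fit"
  )
}

# Per-member score matrix (n x n_models).
mlrnn_member_scores <- function(object, x) {
  vapply(object$members, function(mem) {
    h <- mlrnn_hidden(mem$model, x)
    as.numeric(h %*% mem$readout$weights + mem$readout$bias)
  }, numeric(nrow(x)))
}

#' Predict with a multi-layer RNN classifier
#'
#' @param object An `mlrnn_fit`.
#' @param newdata Feature matrix/data frame in `[0, 1]`.
#' @param threshold Optional override of the fitted threshold.
#' @param ... Unused.
#' @return A tibble with `score` (ensemble-mean) and `label`
#'   (`score >= threshold`); per-member scores in attribute
#'   `member_scores`.
#' @export
predict.mlrnn_fit <- function(object, newdata, threshold = NULL, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$d) {
    stop(sprintf("`newdata` has %d features; the model expects %d",
                 ncol(x), object$d), call. = FALSE)
  }
  thr <- threshold %||% object$threshold
  scores <- mlrnn_member_scores(object, x)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  mean_score <- rowMeans(scores)
  out <- tibble::tibble(score = mean_score,
                        label = as.integer(mean_score >= thr))
  attr(out, "member_scores") <- scores
  out
}

#' Per-member metrics of an MLRNN ensemble
#'
#' Computes sensitivity/specificity/balanced accuracy separately for each
#' ensemble member and appends the trial-averaged row (`member = "mean"`),
#' i.e. the reported metric is the mean of the per-seed metrics.
#'
#' @param object An `mlrnn_fit`.
#' @param x,y Evaluation features and binary labels.
#' @return A tibble with one row per member plus the mean row.
#' @export
ensemble_metrics <- function(object, x, y) {
  x <- as_feature_matrix(x)
  y <- check_binary_labels(y, require_both = FALSE)
  scores <- mlrnn_member_scores(object, x)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  rows <- purrr::map_dfr(seq_len(ncol(scores)), function(m) {
    compute_metrics(y, as.integer(scores[, m] >= object$threshold))
  })
  rows$member <- as.character(seq_len(ncol(scores)))
  mean_row <- dplyr::summarise(rows, dplyr::across(
    c("sensitivity", "specificity", "ba"), ~ mean(.x, na.rm = TRUE)))
  mean_row$member <- "mean"
  dplyr::bind_rows(rows, mean_row)[, c("member", "tp", "fp", "tn", "fn",
                                       "sensitivity", "specificity", "ba")]
}

#' @export
print.mlrnn_fit <- function(x, ...) {
  cat(sprintf("<mlrnn_fit> %d descriptors -> %d inputs -> %d hidden cells | ridge %g | %d member(s)\n",
              x$d, x$members[[1]]$model$n_inputs,
              x$members[[1]]$model$n_hidden, x$ridge, x$n_models))
  invisible(x)
}

#' @method tidy mlrnn_fit
#' @export
tidy.mlrnn_fit <- function(x, ...) {
  ro <- x$members[[1]]$readout
  tibble::tibble(
    term = c(sprintf("hidden_%03d", seq_along(ro$weights)), "(bias)"),
    estimate = c(ro$weights, ro$bias)
  )
}

#' @method glance mlrnn_fit
#' @export
glance.mlrnn_fit <- function(x, ...) {
  tibble::tibble(d = x$d, n_inputs = x$members[[1]]$model$n_inputs,
                 n_hidden = x$members[[1]]$model$n_hidden,
                 ridge = x$ridge, n_models = x$n_models,
                 best_cv_ba = max(x$cv$mean_val_ba, na.rm = TRUE))
}
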
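#' Train a recurrent Random Neural Network classifier
#'
#' Gradient-descent learning on the excitatory and inhibitory weight matrices
#' of a fully recurrent G-Network. Descriptor values (scaled to `[0, 1]`)
#' enter the network as exogenous excitatory arrival rates of the input
#' cells (`lambda_plus[i] = gain * x[i]`); the classifier score is the
#' steady-state excitation probability of a single output cell. The squared
#' error on that probability is minimized by stochastic gradient descent,
#' with the gradients obtained from the linear-system sensitivity equations
#' of the product form; weights are projected back to non-negative values
#' after every update so the object remains a valid G-Network throughout.
#'
#' @param x Feature matrix or data frame, values in `[0, 1]` (character/factor
#'   identifier columns are dropped).
#' @param y Binary labels (0/1); both classes must be present.
#' @param hidden Number of hidden cells. The network has
#'   `ncol(x) + hidden + 1` cells: inputs, hidden, one output.
#' @param lr Learning rate.
#' @param epochs Number of passes over the training set (samples are
#'   reshuffled each epoch).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param gain Scale applied to descriptor values when injected as rates.
#' @param leak Per-cell departure rate added to the row sums to form the
#'   firing rates; keeps every rate strictly positive.
#' @param init_max Upper bound of the uniform weight initialization,
#'   expressed per cell (`runif(0, init_max / n_cells)`).
#' @param threshold Score threshold for the positive class (label 1 when
#'   `score >= threshold`).
#' @param tol,inner_max_iter Fixed-point tolerance and iteration cap used for
#'   the per-sample steady-state solves during training.
#'
#' @return An object of class `rnn_fit` containing the trained
#'   [rnn_network()], a per-epoch trace (`loss` = sum of squared errors / 2,
#'   `ba` = training balanced accuracy, `min_weight`) and the
#'   hyperparameters. Use [predict.rnn_fit()], [tidy()] and [glance()].
#' @export
train_rnn <- function(x, y, hidden = 4, lr = 0.1, epochs = 100, seed = 1,
                      gain = 1, leak = 0.1, init_max = 1, threshold = 0.5,
                      tol = 1e-7, inner_max_iter = 300) {
  x <- as_feature_matrix(x)
  y <- check_binary_labels(y)
  if (nrow(x) != length(y)) stop("`x` and `y` sizes disagree", call. = FALSE)
  stopifnot(hidden >= 0, lr > 0, epochs >= 0, leak > 0)
  d <- ncol(x)
  n_cells <- d + hidden + 1L
  out_cell <- n_cells
  res <- with_seed_(seed, {
    w0 <- init_max / n_cells
    wp <- matrix(runif(n_cells^2, 0, w0), n_cells, n_cells)
    wm <- matrix(runif(n_cells^2, 0, w0), n_cells, n_cells)
    diag(wp) <- 0
    diag(wm) <- 0
    cpp_train_rnn(x, y, wp, wm, as.integer(d), as.integer(out_cell),
                  gain, leak, lr, as.integer(epochs), tol,
                  as.integer(inner_max_iter), threshold)
  })
  net <- rnn_network(w_plus = res$Wp, w_minus = res$Wm, leak = leak,
                     input_cells = seq_len(d), output_cell = out_cell)
  trace <- tibble::tibble(
    epoch = seq_len(epochs),
    loss = as.numeric(res$loss),
    ba = as.numeric(res$ba),
    min_weight = as.numeric(res$min_weight)
  )
  structure(
    list(network = net, trace = trace, n_input = d, gain = gain,
         leak = leak, threshold = threshold,
         hyper = list(hidden = hidden, lr = lr, epochs = epochs, seed = seed,
                      init_max = init_max),
         tol = tol, inner_max_iter = inner_max_iter),
    class = "rnn_fit"
  )
}

#' Predict with a trained RNN classifier
#'
#' Each row of `newdata` is injected as exogenous excitatory rates and the
#' steady state is solved; the score is the output cell's excitation
#' probability and the label applies the `>=` threshold rule. If the network
#' is unstable (saturated) on a sample, the score is clamped at 1 and a
#' warning is raised.
#'
#' @param object An `rnn_fit`.
#' @param newdata Feature matrix/data frame in `[0, 1]`.
#' @param threshold Optional override of the fitted threshold.
#' @param ... Unused.
#' @return A tibble with columns `score`, `label`, `stable`.
#' @export
predict.rnn_fit <- function(object, newdata, threshold = NULL, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$n_input) {
    stop(sprintf("`newdata` has %d features; the model expects %d",
                 ncol(x), object$n_input), call. = FALSE)
  }
  thr <- threshold %||% object$threshold
  net <- object$network
  res <- cpp_predict_rnn(x, net$w_plus, net$w_minus, object$n_input,
                         net$output_cell, object$gain, object$leak,
                         object$tol, as.integer(object$inner_max_iter))
  score <- as.numeric(res$score)
  stable <- as.logical(res$stable)
  if (any(!stable)) {
    warning(sprintf("%d sample(s) drove the network unstable; scores clamped at 1",
                    sum(!stable)), call. = FALSE)
  }
  tibble::tibble(score = score, label = as.integer(score >= thr),
                 stable = stable)
}

#' @export
print.rnn_fit <- function(x, ...) {
  cat(sprintf("<rnn_fit> %d input + %d hidden + 1 output cells | %d epochs\n",
              x$n_input, x$hyper$hidden, x$hyper$epochs))
  if (nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final loss %.4g | training BA %.3f\n", last$loss, last$ba))
  }
  invisible(x)
}

#' @method tidy rnn_fit
#' @export
tidy.rnn_fit <- function(x, ...) x$trace

#' @method glance rnn_fit
#' @export
glance.rnn_fit <- function(x, ...) {
  last <- if (nrow(x$trace) > 0) x$trace[nrow(x$trace), ] else
    tibble::tibble(loss = NA_real_, ba = NA_real_, min_weight = NA_real_)
  tibble::tibble(n_cells = x$network$n_cells, hidden = x$hyper$hidden,
                 epochs = x$hyper$epochs, lr = x$hyper$lr,
                 final_loss = last$loss, final_ba = last$ba,
                 min_weight = last$min_weight)
}

#' Cross-validated hyperparameter selection for the RNN classifier
#'
#' Stratified k-fold cross-validation over a grid of `(hidden, lr, epochs)`
#' gradient-descent settings. The grid point with the highest mean validation
#' balanced accuracy wins; ties go to the smallest `hidden`, then the
#' smallest `epochs`. The winner is refit on all the data.
#'
#' @inheritParams train_rnn
#' @param grid Data frame with columns `hidden`, `lr`, `epochs` (one row per
#'   candidate).
#' @param folds Number of stratified folds (>= 2).
#' @param ... Passed on to [train_rnn()] (e.g. `gain`, `leak`).
#' @return A list of class `rnn_cv`: `best` (one-row tibble), `results`
#'   (grid with mean validation BA), `fit` (the refit [train_rnn()] object).
#' @export
cv_select_rnn <- function(x, y, grid, folds = 3, seed = 1, ...) {
  x <- as_feature_matrix(x)
  y <- check_binary_labels(y)
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  stopifnot(all(c("hidden", "lr", "epochs") %in% names(grid)))
  fold <- make_folds(y, folds, seed)
  mean_ba <- vapply(seq_len(nrow(grid)), function(g) {
    bas <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- train_rnn(x[tr, , drop = FALSE], y[tr],
                       hidden = grid$hidden[g], lr = grid$lr[g],
                       epochs = grid$epochs[g], seed = seed, ...)
      pred <- suppressWarnings(predict(fit, x[!tr, , drop = FALSE]))
      m <- compute_metrics(y[!tr], pred$label)
      m$ba
    }, numeric(1))
    mean(bas, na.rm = TRUE)
  }, numeric(1))
  results <- dplyr::mutate(grid, mean_val_ba = mean_ba)
  ord <- order(-results$mean_val_ba, results$hidden, results$epochs)
  best <- results[ord[1], ]
  fit <- train_rnn(x, y, hidden = best$hidden, lr = best$lr,
                   epochs = best$epochs, seed = seed, ...)
  structure(list(best = best, results = results, fit = fit, folds = folds,
                 seed = seed),
            class = "rnn_cv")
}

#' @export
print.rnn_cv <- function(x, ...) {
  cat(sprintf("<rnn_cv> %d grid points, %d folds\n", nrow(x$results), x$folds))
  cat(sprintf("  best: hidden=%d lr=%g epochs=%d (mean val BA %.3f)\n",
              x$best$hidden, x$best$lr, x$best$epochs, x$best$mean_val_ba))
  invisible(x)
}

#' @method tidy rnn_cv
#' @export
tidy.rnn_cv <- function(x, ...) x$results
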
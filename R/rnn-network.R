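#' Construct a G-Network / Random Neural Network
#'
#' A G-Network is a queueing network of spiking cells. Each cell holds a
#' non-negative integer potential; excitatory spikes add one to the target's
#' potential and inhibitory spikes subtract one (floored at zero). Cell `i`
#' receives exogenous excitatory Poisson arrivals at rate `lambda_plus[i]` and
#' inhibitory arrivals at rate `lambda_minus[i]`, and fires with exponential
#' rate `rate[i]` whenever its potential is positive. A firing event routes a
#' spike to cell `j` as excitatory with probability `w_plus[i, j] / rate[i]`,
#' as inhibitory with probability `w_minus[i, j] / rate[i]`, or leaves the
#' network with the remaining probability (the leak).
#'
#' The total firing rate must dominate the synaptic rates:
#' `rate[i] = rowSums(w_plus + w_minus)[i] + leak[i]` with `leak[i] >= 0`.
#' If `rate` is omitted it is built from the row sums plus `leak`.
#'
#' @param w_plus,w_minus Square matrices of non-negative excitatory /
#'   inhibitory synaptic rates (events per unit time); zero diagonal.
#' @param lambda_plus,lambda_minus Exogenous excitatory / inhibitory Poisson
#'   arrival rates, one per cell (recycled if scalar).
#' @param rate Total firing rates, one per cell, strictly positive. Defaults
#'   to row sums of the weights plus `leak`.
#' @param leak Non-negative departure rate per cell used when `rate` is not
#'   given. Default 0.1 keeps every firing rate strictly positive.
#' @param input_cells Indices of cells where descriptor values enter as
#'   exogenous excitatory rates.
#' @param output_cell Index of the cell whose excitation probability is the
#'   classifier score. Defaults to the last cell.
#'
#' @return An object of class `rnn_network`.
#' @seealso [solve_fixed_point()], [simulate_network()]
#' @examples
#' net <- rnn_network(w_plus = matrix(0, 1, 1), w_minus = matrix(0, 1, 1),
#'                    lambda_plus = 0.4, lambda_minus = 0.1, rate = 1)
#' solve_fixed_point(net)$q  # 0.4 / 1.1
#' @export
rnn_network <- function(w_plus, w_minus, lambda_plus = 0, lambda_minus = 0,
                        rate = NULL, leak = 0.1, input_cells = integer(),
                        output_cell = NULL) {
  w_plus <- as.matrix(w_plus)
  w_minus <- as.matrix(w_minus)
  n <- nrow(w_plus)
  if (ncol(w_plus) != n || !identical(dim(w_minus), dim(w_plus))) {
    stop("`w_plus` and `w_minus` must be square matrices of the same size",
         call. = FALSE)
  }
  lambda_plus <- rep_len(as.double(lambda_plus), n)
  lambda_minus <- rep_len(as.double(lambda_minus), n)
  leak <- rep_len(as.double(leak), n)
  if (!all(is.finite(w_plus)) || !all(is.finite(w_minus)) ||
      !all(is.finite(lambda_plus)) || !all(is.finite(lambda_minus))) {
    stop("network rates must be finite", call. = FALSE)
  }
  if (min(w_plus) < 0 || min(w_minus) < 0 || min(lambda_plus) < 0 ||
      min(lambda_minus) < 0 || min(leak) < 0) {
    stop("all rates must be non-negative", call. = FALSE)
  }
  if (any(diag(w_plus) != 0) || any(diag(w_minus) != 0)) {
    stop("self-loops are not allowed: weight diagonals must be zero",
         call. = FALSE)
  }
  row_out <- rowSums(w_plus) + rowSums(w_minus)
  if (is.null(rate)) {
    rate <- row_out + leak
  } else {
    rate <- rep_len(as.double(rate), n)
    if (any(rate <= 0)) stop("firing rates must be strictly positive", call. = FALSE)
    if (any(rate < row_out - 1e-12)) {
      stop("firing rate below the row sum of synaptic weights (leak would be negative)",
           call. = FALSE)
    }
  }
  if (any(rate <= 0)) {
    stop("firing rates must be strictly positive; increase `leak`", call. = FALSE)
  }
  output_cell <- if (is.null(output_cell)) n else as.integer(output_cell)
  stopifnot(output_cell >= 1, output_cell <= n)
  input_cells <- as.integer(input_cells)
  stopifnot(all(input_cells >= 1), all(input_cells <= n))
  structure(
    list(n_cells = n, w_plus = w_plus, w_minus = w_minus,
         lambda_plus = lambda_plus, lambda_minus = lambda_minus,
         rate = rate, input_cells = input_cells, output_cell = output_cell),
    class = "rnn_network"
  )
}

#' @export
print.rnn_network <- function(x, ...) {
  cat(sprintf("<rnn_network> %d cells, %d input(s), output cell %d\n",
              x$n_cells, length(x$input_cells), x$output_cell))
  cat(sprintf("  total synaptic rate: %.4g (excitatory) / %.4g (inhibitory)\n",
              sum(x$w_plus), sum(x$w_minus)))
  invisible(x)
}

#' Product-form steady state by fixed-point iteration
#'
#' Computes the excitation probabilities `q` of a G-Network by damped
#' successive substitution on the product-form map
#' `q[i] <- min(1, lam_plus[i] / (rate[i] + lam_minus[i]))` where
#' `lam_plus = t(w_plus) %*% q + lambda_plus` and
#' `lam_minus = t(w_minus) %*% q + lambda_minus`.
#'
#' @param net An [rnn_network()].
#' @param tol Convergence tolerance on the max absolute change per sweep.
#' @param max_iter Iteration cap.
#' @param damping Step fraction in (0, 1]; 1 is plain substitution.
#'
#' @return An object of class `rnn_steady_state`: a list with `q` (clamped to
#'   `[0, 1]`), `residual`, `iterations`, `converged`, and `stable` (`FALSE`
#'   when any unclamped ratio reaches 1, i.e. a saturated cell).
#' @export
solve_fixed_point <- function(net, tol = 1e-8, max_iter = 10000, damping = 1) {
  stopifnot(inherits(net, "rnn_network"), tol > 0, max_iter >= 1,
            damping > 0, damping <= 1)
  res <- cpp_solve_fixed_point(net$w_plus, net$w_minus, net$lambda_plus,
                               net$lambda_minus, net$rate, tol,
                               as.integer(max_iter), damping)
  structure(
    list(q = as.numeric(res$q), residual = res$residual,
         iterations = res$iterations, converged = res$converged,
         stable = res$stable, n_cells = net$n_cells,
         output_cell = net$output_cell),
    class = "rnn_steady_state"
  )
}

#' @export
print.rnn_steady_state <- function(x, ...) {
  cat(sprintf("<rnn_steady_state> %d cells | converged: %s (%d iterations, residual %.3g)%s\n",
              x$n_cells, x$converged, x$iterations, x$residual,
              if (!x$stable) " | UNSTABLE (saturated cell)" else ""))
  print(round(x$q, 6))
  invisible(x)
}

#' @method tidy rnn_steady_state
#' @export
tidy.rnn_steady_state <- function(x, ...) {
  tibble::tibble(cell = seq_len(x$n_cells), q = x$q)
}

#' @method glance rnn_steady_state
#' @export
glance.rnn_steady_state <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, residual = x$residual,
                 iterations = x$iterations, converged = x$converged,
                 stable = x$stable, q_output = x$q[x$output_cell])
}

#' Discrete-event simulation of the G-Network Markov chain
#'
#' Simulates the continuous-time Markov chain underlying an [rnn_network()]
#' (exogenous Poisson arrivals, exponential firing, spike routing by the
#' weight matrices) and returns the time-averaged fraction of time each
#' cell's potential exceeds zero. This is an independent estimate of the
#' steady-state excitation probabilities of [solve_fixed_point()], used to
#' validate the product-form solution.
#'
#' Standard errors are batch means over `n_batches` equal windows of the
#' horizon, which absorbs the autocorrelation of the occupancy process.
#'
#' @inheritParams solve_fixed_point
#' @param horizon Simulated time; should be much larger than the inverse of
#'   the smallest positive rate.
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @param n_batches Number of batch-mean windows for the standard error.
#'
#' @return A tibble with columns `cell`, `q` (empirical occupancy) and `se`,
#'   with the event count in attribute `n_events`.
#' @export
simulate_network <- function(net, horizon = 1e5, seed = 1, n_batches = 50) {
  stopifnot(inherits(net, "rnn_network"), horizon > 0, n_batches >= 2)
  total_rate <- sum(net$lambda_plus) + sum(net$lambda_minus) + sum(net$rate)
  if (total_rate <= 0) stop("zero total event rate: nothing to simulate", call. = FALSE)
  res <- with_seed_(seed, {
    cpp_simulate_network(net$w_plus, net$w_minus, net$lambda_plus,
                         net$lambda_minus, net$rate, horizon,
                         as.integer(n_batches))
  })
  out <- tibble::tibble(cell = seq_len(net$n_cells),
                        q = as.numeric(res$q), se = as.numeric(res$se))
  attr(out, "n_events") <- res$n_events
  attr(out, "horizon") <- horizon
  out
}

#' Read and write a network description as YAML
#'
#' Serializes the rates, weights and cell roles of an [rnn_network()] so a
#' network can be shipped to the command line tools (`gnetox rnn-solve`,
#' `gnetox rnn-simulate`).
#'
#' @param net An [rnn_network()].
#' @param path File path.
#' @return `write_network_yaml()` returns `net` invisibly;
#'   `read_network_yaml()` returns an [rnn_network()].
#' @export
write_network_yaml <- function(net, path) {
  stopifnot(inherits(net, "rnn_network"))
  doc <- list(
    n_cells = net$n_cells,
    w_plus = apply(net$w_plus, 1, as.numeric, simplify = FALSE),
    w_minus = apply(net$w_minus, 1, as.numeric, simplify = FALSE),
    lambda_plus = as.numeric(net$lambda_plus),
    lambda_minus = as.numeric(net$lambda_minus),
    rate = as.numeric(net$rate),
    input_cells = as.integer(net$input_cells),
    output_cell = as.integer(net$output_cell)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(net)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  n <- doc$n_cells
  to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
  rnn_network(
    w_plus = to_mat(doc$w_plus), w_minus = to_mat(doc$w_minus),
    lambda_plus = as.numeric(doc$lambda_plus),
    lambda_minus = as.numeric(doc$lambda_minus),
    rate = as.numeric(doc$rate),
    input_cells = as.integer(doc$input_cells %||% integer()),
    output_cell = as.integer(doc$output_cell %||% n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
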
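# Fixtures built in code: random stable G-Networks, separable blobs, and
# independent oracles used across the test files.

# Random stable network of n cells: firing rates dominate the synaptic row
# sums by a positive leak, so excitation ratios stay below 1.
random_stable_network <- function(n, seed, w_max = 0.3) {
  set.seed(seed)
  wp <- matrix(runif(n^2, 0, w_max), n, n)
  wm <- matrix(runif(n^2, 0, w_max), n, n)
  diag(wp) <- 0
  diag(wm) <- 0
  rnn_network(wp, wm,
              lambda_plus = runif(n, 0.05, 0.3),
              lambda_minus = runif(n, 0, 0.2),
              leak = runif(n, 0.3, 1))
}

# Two well-separated Gaussian blobs in [0,1]^2.
make_blobs <- function(n = 40, seed = 1, sd = 0.07) {
  set.seed(seed)
  n2 <- n %/% 2
  x <- rbind(cbind(rnorm(n2, 0.25, sd), rnorm(n2, 0.25, sd)),
             cbind(rnorm(n - n2, 0.75, sd), rnorm(n - n2, 0.75, sd)))
  x <- pmin(pmax(x, 0), 1)
  list(x = x, y = rep(c(0L, 1L), c(n2, n - n2)))
}

# Closed-form cascade evaluation for feed-forward (strictly upper-triangular
# weight) networks: cells are solved in topological order, so this is an
# independent oracle for the fixed-point solver.
cascade_solve <- function(net) {
  n <- net$n_cells
  q <- numeric(n)
  for (i in seq_len(n)) {
    lam_p <- net$lambda_plus[i] + sum(q * net$w_plus[, i])
    lam_m <- net$lambda_minus[i] + sum(q * net$w_minus[, i])
    q[i] <- min(1, lam_p / (net$rate[i] + lam_m))
  }
  q
}

# Exhaustive maximum complete submatrix over row subsets: for every nonempty
# subset of rows keep all columns complete on those rows and count cells.
max_complete_cells <- function(m) {
  n <- nrow(m)
  best <- 0
  for (bits in seq_len(2^n - 1)) {
    rows <- which(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0)
    sub <- m[rows, , drop = FALSE]
    cols_ok <- colSums(is.na(sub)) == 0
    best <- max(best, length(rows) * sum(cols_ok))
  }
  best
}

# Brute-force confusion tally by explicit looping (oracle for compute_metrics).
tally_confusion <- function(y_true, y_pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# A small incomplete AC50 table with identifier column.
toy_ac50 <- function(n = 8, m = 5, miss = 0.2, seed = 1) {
  set.seed(seed)
  ac <- matrix(ifelse(runif(n * m) < 0.2, 10^runif(n * m, -2, 1), 1e6), n, m)
  ac[runif(n * m) < miss] <- NA
  colnames(ac) <- sprintf("assay_%02d", seq_len(m))
  dplyr::bind_cols(tibble::tibble(compound_id = sprintf("C%03d", seq_len(n))),
                   tibble::as_tibble(as.data.frame(ac)))
}
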
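// G-Network / Random Neural Network numerical core.
//
// Cells hold a non-negative integer potential. Excitatory spikes (rate
// weights w+) add 1 at the target, inhibitory spikes (w-) subtract 1 floored
// at 0; exogenous Poisson arrivals Lambda (excitatory) and lambda
// (inhibitory) drive the network; a cell with positive potential fires with
// exponential rate r(i). In steady state the excitation probabilities solve
// the product-form fixed point
//
//   q(i) = min(1, lam_plus(i) / (r(i) + lam_minus(i)))
//   lam_plus(i)  = sum_j q(j) w+(j,i) + Lambda(i)
//   lam_minus(i) = sum_j q(j) w-(j,i) + lambda(i)
//
// All randomness goes through R's RNG (unif_rand / exp_rand) so set.seed()
// on the R side makes every routine reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Damped successive substitution on the product-form map.
static void fp_iterate(const arma::mat& Wp, const arma::mat& Wm,
                       const arma::vec& Lp, const arma::vec& Lm,
                       const arma::vec& r, double tol, int max_iter,
                       double damping, arma::vec& q, double& residual,
                       int& iterations, bool& converged, bool& stable) {
  const arma::uword n = r.n_elem;
  residual = R_PosInf;
  iterations = 0;
  converged = false;
  stable = true;
  arma::vec ratio(n);
  for (int it = 0; it < max_iter; ++it) {
    arma::vec lam_p = Wp.t() * q + Lp;
    arma::vec lam_m = Wm.t() * q + Lm;
    arma::vec denom = r + lam_m;
    for (arma::uword i = 0; i < n; ++i) {
      if (denom[i] <= 0.0) {
        if (lam_p[i] > 0.0)
          stop("degenerate network: cell %d has r + lambda_minus = 0 but positive excitatory input", (int)(i + 1));
        ratio[i] = 0.0;
      } else {
        ratio[i] = lam_p[i] / denom[i];
      }
    }
    arma::vec q_new = arma::clamp(ratio, 0.0, 1.0);
    q_new = (1.0 - damping) * q + damping * q_new;
    residual = arma::abs(q_new - q).max();
    q = q_new;
    iterations = it + 1;
    if (residual <= tol) {
      converged = true;
      break;
    }
  }
  // stability assessed at the final iterate: any unclamped ratio >= 1
  arma::vec lam_p = Wp.t() * q + Lp;
  arma::vec lam_m = Wm.t() * q + Lm;
  for (arma::uword i = 0; i < n; ++i) {
    double denom = r[i] + lam_m[i];
    if (denom > 0.0 && lam_p[i] / denom >= 1.0) stable = false;
  }
}

// [[Rcpp::export]]
List cpp_solve_fixed_point(const arma::mat& Wp, const arma::mat& Wm,
                           const arma::vec& Lp, const arma::vec& Lm,
                           const arma::vec& r, double tol, int max_iter,
                           double damping) {
  arma::vec q(r.n_elem, arma::fill::zeros);
  double residual;
  int iterations;
  bool converged, stable;
  fp_iterate(Wp, Wm, Lp, Lm, r, tol, max_iter, damping, q, residual,
             iterations, converged, stable);
  return List::create(_["q"] = q, _["residual"] = residual,
                      _["iterations"] = iterations,
                      _["converged"] = converged, _["stable"] = stable);
}

// Continuous-time Markov chain simulation; returns time-averaged occupancy
// (fraction of time potential > 0) per cell plus a batch-means standard
// error over n_batches equal-length windows.
// [[Rcpp::export]]
List cpp_simulate_network(const arma::mat& Wp, const arma::mat& Wm,
                          const arma::vec& Lp, const arma::vec& Lm,
                          const arma::vec& r, double horizon, int n_batches) {
  const arma::uword n = r.n_elem;
  arma::ivec k(n, arma::fill::zeros);
  arma::mat batch_occ(n, n_batches, arma::fill::zeros);
  const double batch_len = horizon / n_batches;
  // firing routing: cumulative probabilities per source cell
  arma::vec row_out(n);  // total outgoing weight + leak = r(i)
  for (arma::uword i = 0; i < n; ++i) row_out[i] = r[i];

  double t = 0.0;
  long n_events = 0;
  RNGScope scope;
  while (t < horizon) {
    double total = arma::accu(Lp);
    for (arma::uword i = 0; i < n; ++i)
      if (k[i] > 0) total += Lm[i] + r[i];
    if (total <= 0.0) {
      // absorbing all-empty state with no excitatory input: occupancy stays 0
      break;
    }
    double dt = exp_rand() / total;
    double t_end = std::min(t + dt, horizon);
    // accumulate occupancy, splitting across batch boundaries
    double a = t;
    while (a < t_end) {
      int b = std::min((int)(a / batch_len), n_batches - 1);
      double b_hi = std::min((double)(b + 1) * batch_len, t_end);
      for (arma::uword i = 0; i < n; ++i)
        if (k[i] > 0) batch_occ(i, b) += (b_hi - a);
      a = b_hi;
    }
    t += dt;
    if (t >= horizon) break;
    ++n_events;
    double u = unif_rand() * total;
    bool done = false;
    for (arma::uword i = 0; i < n && !done; ++i) {
      if (u < Lp[i]) { k[i] += 1; done = true; break; }
      u -= Lp[i];
    }
    if (!done) {
      for (arma::uword i = 0; i < n && !done; ++i) {
        if (k[i] == 0) continue;
        if (u < Lm[i]) {
          k[i] -= 1;
          done = true;
          break;
        }
        u -= Lm[i];
        if (u < r[i]) {
          // cell i fires: potential drops, spike routed by weights
          k[i] -= 1;
          double v = unif_rand() * r[i];
          bool routed = false;
          for (arma::uword j = 0; j < n && !routed; ++j) {
            if (v < Wp(i, j)) { k[j] += 1; routed = true; break; }
            v -= Wp(i, j);
          }
          if (!routed) {
            for (arma::uword j = 0; j < n && !routed; ++j) {
              if (v < Wm(i, j)) {
                if (k[j] > 0) k[j] -= 1;
                routed = true;
                break;
              }
              v -= Wm(i, j);
            }
          }
          // remaining mass = leak d(i): spike leaves the network
          done = true;
          break;
        }
        u -= r[i];
      }
    }
  }
  arma::mat batch_frac = batch_occ / batch_len;
  arma::vec q_emp = arma::mean(batch_frac, 1);
  arma::vec se(n);
  for (arma::uword i = 0; i < n; ++i) {
    arma::rowvec bi = batch_frac.row(i);
    se[i] = arma::stddev(bi) / std::sqrt((double)n_batches);
  }
  return List::create(_["q"] = q_emp, _["se"] = se,
                      _["n_events"] = (double)n_events,
                      _["n_batches"] = n_batches);
}

// Gradient of the output cell's q with respect to every weight, via the
// linear-system formulation: with D(i) = r(i) + lam_minus(i) and
// A(j,i) = (w+(j,i) - q(i) w-(j,i)) / D(i), the row vector g = dq/dtheta
// satisfies g = g A + b, so g_out = b . x where (I - A) x = e_out.
// For theta = w+(u,v):  dq_out = q(u) (x(v)/D(v) - x(u)/D(u))
// For theta = w-(u,v):  dq_out = -q(u) (x(u)/D(u) + q(v) x(v)/D(v))
//
// Recurrent SGD over samples; weights projected to >= 0 after each update,
// diagonal kept at zero, r recomputed as row sums + leak.
// [[Rcpp::export]]
List cpp_train_rnn(const arma::mat& X, const arma::ivec& y, arma::mat Wp,
                   arma::mat Wm, int n_input, int out_cell, double gain,
                   double leak, double lr, int epochs, double tol,
                   int inner_max_iter, double threshold) {
  const arma::uword n_cells = Wp.n_rows;
  const arma::uword n_obs = X.n_rows;
  const int out = out_cell - 1;  // 0-based
  arma::vec loss_trace(std::max(epochs, 0), arma::fill::zeros);
  arma::vec ba_trace(std::max(epochs, 0), arma::fill::zeros);
  arma::vec min_w_trace(std::max(epochs, 0), arma::fill::zeros);
  arma::vec Lm(n_cells, arma::fill::zeros);
  arma::uvec order(n_obs);
  for (arma::uword i = 0; i < n_obs; ++i) order[i] = i;
  RNGScope scope;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    for (arma::uword i = n_obs - 1; i > 0; --i) {
      arma::uword j = (arma::uword)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    double tp = 0, fn = 0, tn = 0, fp = 0;
    for (arma::uword s = 0; s < n_obs; ++s) {
      arma::uword idx = order[s];
      arma::vec Lp(n_cells, arma::fill::zeros);
      for (int f = 0; f < n_input; ++f) Lp[f] = gain * X(idx, f);
      arma::vec r = arma::sum(Wp + Wm, 1) + leak;
      arma::vec q(n_cells, arma::fill::zeros);
      double residual;
      int iterations;
      bool converged, stable;
      fp_iterate(Wp, Wm, Lp, Lm, r, tol, inner_max_iter, 1.0, q, residual,
                 iterations, converged, stable);
      arma::vec lam_m = Wm.t() * q + Lm;
      arma::vec D = r + lam_m;
      // A(j,i) = (Wp(j,i) - q(i) Wm(j,i)) / D(i)
      arma::mat A = Wp;
      for (arma::uword i = 0; i < n_cells; ++i)
        A.col(i) = (Wp.col(i) - q[i] * Wm.col(i)) / D[i];
      arma::vec e(n_cells, arma::fill::zeros);
      e[out] = 1.0;
      arma::vec xsol;
      bool ok = arma::solve(xsol, arma::eye(n_cells, n_cells) - A, e,
                            arma::solve_opts::no_approx);
      if (!ok) continue;  // singular sensitivity system: skip update
      arma::vec a = xsol / D;
      double err = q[out] - (double)y[idx];
      ep_loss += 0.5 * err * err;
      double score = q[out];
      if (y[idx] == 1) { if (score >= threshold) tp += 1; else fn += 1; }
      else             { if (score >= threshold) fp += 1; else tn += 1; }
      // outer-product gradients
      arma::vec qa = q % a;
      arma::mat Gp = q * a.t();
      Gp.each_col() -= qa;
      arma::mat Gm = -(qa * arma::ones<arma::rowvec>(n_cells));
      Gm -= q * qa.t();
      Wp -= lr * err * Gp;
      Wm -= lr * err * Gm;
      Wp.transform([](double w) { return w < 0.0 ? 0.0 : w; });
      Wm.transform([](double w) { return w < 0.0 ? 0.0 : w; });
      Wp.diag().zeros();
      Wm.diag().zeros();
    }
    if (!std::isfinite(ep_loss))
      stop("training diverged: non-finite loss at epoch %d", ep + 1);
    loss_trace[ep] = ep_loss;
    double sens = (tp + fn > 0) ? tp / (tp + fn) : NA_REAL;
    double spec = (tn + fp > 0) ? tn / (tn + fp) : NA_REAL;
    ba_trace[ep] = (sens + spec) / 2.0;
    min_w_trace[ep] = std::min(Wp.min(), Wm.min());
  }
  return List::create(_["Wp"] = Wp, _["Wm"] = Wm, _["loss"] = loss_trace,
                      _["ba"] = ba_trace, _["min_weight"] = min_w_trace);
}

// Batch prediction: one fixed-point solve per row.
// [[Rcpp::export]]
List cpp_predict_rnn(const arma::mat& X, const arma::mat& Wp,
                     const arma::mat& Wm, int n_input, int out_cell,
                     double gain, double leak, double tol, int max_iter) {
  const arma::uword n_cells = Wp.n_rows;
  const arma::uword n_obs = X.n_rows;
  const int out = out_cell - 1;
  arma::vec r = arma::sum(Wp + Wm, 1) + leak;
  arma::vec Lm(n_cells, arma::fill::zeros);
  arma::vec scores(n_obs);
  LogicalVector stable_flags(n_obs);
  for (arma::uword i = 0; i < n_obs; ++i) {
    arma::vec Lp(n_cells, arma::fill::zeros);
    for (int f = 0; f < n_input; ++f) Lp[f] = gain * X(i, f);
    arma::vec q(n_cells, arma::fill::zeros);
    double residual;
    int iterations;
    bool converged, stable;
    fp_iterate(Wp, Wm, Lp, Lm, r, tol, max_iter, 1.0, q, residual,
               iterations, converged, stable);
    scores[i] = q[out];
    stable_flags[i] = stable;
  }
  return List::create(_["score"] = scores, _["stable"] = stable_flags);
}
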
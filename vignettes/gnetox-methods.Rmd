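---
title: "G-Network classifiers for bioactivity screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G-Network classifiers for bioactivity screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnetox)
```

## The problem

High-throughput in vitro screening programs such as the US EPA's ToxCast
measure, for thousands of chemical compounds, the concentration at which each
compound produces half-maximal activity in a panel of biochemical assays (the
AC50). A compound with no measurable response is recorded with the sentinel
value 1,000,000. QSAR (quantitative structure–activity relationship)
classification asks: can the binary outcome — active or inactive in a given
assay — be predicted from the compound's structural descriptors alone? Two
features make this hard in practice: the assay matrix is riddled with missing
measurements, and the active fraction per assay is small (typically 5–30%, mean
near 12%), so naive classifiers learn to call everything inactive.

`gnetox` implements a complete pipeline for this problem built around
G-Network (Random Neural Network) classifiers: data curation, class balancing
by SMOTE, two RNN model families plus a boosted-trees adapter, and a
repeated-split benchmark harness reporting sensitivity, specificity and
balanced accuracy.

## The G-Network model

A G-Network is a queueing network of spiking cells. Cell $i$ holds a
non-negative integer potential $k_i$. Excitatory spikes arriving at a cell add
one to its potential; inhibitory spikes subtract one, floored at zero.
Exogenous excitatory and inhibitory arrivals are Poisson with rates
$\Lambda_i$ and $\lambda_i$; a cell with positive potential fires after an
exponential delay with rate $r_i$, sending a spike that is excitatory toward
cell $j$ with probability $w^+_{ij}/r_i$, inhibitory with probability
$w^-_{ij}/r_i$, or leaves the network with the remaining leak probability, so
$r_i = \sum_j (w^+_{ij} + w^-_{ij}) + d_i$ with leak $d_i \ge 0$.

The stationary distribution has product form: each cell's marginal excitation
probability $q_i = P(k_i > 0)$ solves the nonlinear fixed point

$$
q_i \;=\; \min\!\left(1,\; \frac{\lambda^+_i}{r_i + \lambda^-_i}\right),
\qquad
\lambda^+_i = \sum_j q_j w^+_{ji} + \Lambda_i,
\qquad
\lambda^-_i = \sum_j q_j w^-_{ji} + \lambda_i .
$$

`solve_fixed_point()` solves this by damped successive substitution (damping
1 by default, tolerance $10^{-8}$ on the max componentwise change, cap 10,000
sweeps) — the simplest scheme consistent with the fixed-point character of the
equations. A cell whose unclamped ratio reaches 1 is saturated; the solution
is clamped into $[0,1]$ and flagged `stable = FALSE` rather than aborted,
which keeps training robust when a gradient step makes a network transiently
unstable. The guard against $r_i + \lambda^-_i = 0$ with positive excitatory
input raises a degenerate-network error.

`simulate_network()` is the independent check on the product form: it runs the
continuous-time Markov chain event by event and reports the time-averaged
fraction of time each potential is positive, with batch-means standard errors
(50 equal windows of the horizon, which absorbs the autocorrelation of the
occupancy process). The solver and the simulator are developed from the same
model but through entirely different mathematics, so their agreement within
Monte-Carlo error on random stable networks — and the exact agreement of the
solver with closed forms on single cells and feed-forward cascades — is the
package's core correctness evidence.

## The recurrent RNN classifier

`train_rnn()` learns a fully recurrent G-Network. Descriptor vectors, scaled
to $[0,1]$ by curation, enter as exogenous excitatory rates of the input
cells ($\Lambda_i = c\,x_i$ with gain $c = 1$); the classifier score is the
output cell's steady-state $q$. The squared error on that score is minimized
by stochastic gradient descent on $w^\pm$. Differentiating the product form
gives, for a parameter $\theta$, a linear system $g = gA + b$ with
$A_{ji} = (w^+_{ji} - q_i w^-_{ji})/D_i$ and $D_i = r_i + \lambda^-_i$; only
the output component is needed, so one solve of $(I - A)\,x = e_{\text{out}}$
per sample prices every weight gradient as an outer product. After each update
the weights are projected to $\ge 0$ (a G-Network has no negative rates), the
diagonal is re-zeroed, and the firing rates are rebuilt as row sums plus a
fixed leak of 0.1, which keeps every rate strictly positive even for an
all-zero input row. The implementation verifies this gradient against finite
differences through the fixed point in the test suite.

Choices a user may care about:

* **Initialization** — weights uniform on $[0, 1/n_{\text{cells}}]$, so
  initial row sums are $O(1)$ and the output cell starts mid-range rather
  than saturated.
* **Threshold** — label 1 when score $\ge 0.5$; ties go to the positive
  class. Configurable per prediction call.
* **Hyperparameters** — `hidden = 4`, `lr = 0.1`, `epochs = 100` by default;
  `cv_select_rnn()` performs stratified cross-validation over a
  `(hidden, lr, epochs)` grid, maximizing mean validation balanced accuracy
  with ties broken toward the smaller architecture and fewer epochs. CV over
  gradient-descent hyperparameters is this package's reading of
  "cross-validation-determined weights" for the recurrent model; the
  literature leaves the exact procedure open, and we document rather than
  assert it.
* **One output cell** encodes the binary decision; a two-output variant was
  considered and rejected as adding parameters without changing the decision
  boundary expressible through a threshold.

## The multi-layer RNN (MLRNN)

The MLRNN fixes its random structure and trains only a linear readout, in the
spirit of extreme-learning machines. Its architecture is fixed at 20 inputs
and 100 intermediate cells. Since descriptor tables have hundreds of columns,
"20 inputs" is realized as a fixed non-negative random projection: a
$d \times 20$ uniform matrix with columns normalized to sum to one, so each
input is a weighted average of descriptors and remains a valid non-negative
rate in $[0,1]$. Each hidden cell $h$ receives excitatory drive
$u^\top W^+_{\cdot h}$ and inhibitory drive $u^\top W^-_{\cdot h}$ from the
projected inputs $u$, with $W^\pm$ independent uniform $[0,1]$ matrices, and
responds with the single-cell transfer
$\min(1,\, x^+ / (r + x^-))$ at firing rate $r = 1$. The readout solves ridge
least squares on the hidden activations; the bias column is left unpenalized
so that as the ridge grows the model degenerates to predicting the base rate,
a property the tests check numerically. The ridge strength is chosen by
stratified cross-validation on balanced accuracy, and `n_models` independently
seeded networks can be averaged — `ensemble_metrics()` reports the mean of
per-seed metrics, the trial-averaging convention used with this model family
(20 trials being the customary count).

A least-squares readout rather than backpropagation is a deliberate design
choice: it matches the fixed-structure, low-cost character of the model and
makes training deterministic given the seed.

## SMOTE balancing

`smote_augment()` is a from-scratch SMOTE: each synthetic sample is
$p + u\,(n - p)$ for a random minority point $p$, a uniform draw $u$, and $n$
one of $p$'s $k = 5$ nearest minority neighbors by Euclidean distance on the
full feature vector (ties broken by row index for determinism). Counts are
balanced to the target ratio exactly, originals are preserved first, and
fractional values on binary fingerprint columns are *kept*: the synthetic
cloud is continuous, which is how the widely used toolbox implementations
behave. $k = 5$ is SMOTE's canonical default. Only training partitions are
ever augmented; the harness keeps the paired test partitions byte-identical
between conditions, which is what makes before/after comparisons honest.

## Curation

`curate()` fixes the pipeline order: complete-submatrix extraction →
binarization → assay filter → fingerprint filter → normalization.

* **Complete submatrix.** The maximum complete submatrix problem is NP-hard,
  so the package uses a greedy heuristic: repeatedly delete the row or column
  with the largest missing fraction (ties: larger absolute count, then column
  before row, then lowest index). On random 7×7 masks the greedy result is
  complete and empirically retains well over 60% of the exhaustive-search
  optimum's cell count — the test suite checks exactly this on 20 seeded
  masks.
* **Binarization.** Label 0 iff AC50 $\ge$ 1,000,000 with relative tolerance
  $10^{-9}$ (so CSV round-trips cannot flip a sentinel), else 1.
* **Prevalence filters.** "Fewer than 5%" is read strictly: an assay or
  fingerprint at exactly 5% is kept.
* **Normalization.** Per-column min–max to $[0,1]$; constant columns map
  to 0. Statistics are attached for reuse, supporting both dataset-level
  fitting (the default, matching how such descriptor tables are usually
  prepared) and train-only fitting for stricter leak-free protocols.

## The benchmark harness

`make_splits()` draws `r_splits` (default 50) independent random partitions;
stratification allocates the test quota of `round(n * test_frac)` (default
test fraction 0.25, a documented assumption) across classes by largest
remainder, guaranteeing both classes on both sides even at 5% prevalence.
`run_benchmark()` trains each requested method on each training partition —
optionally SMOTE-balanced — and scores the untouched test partition;
`compare_augmentation()` runs both conditions with the same seed so the test
partitions are identical. Metrics with empty denominators (no positives in a
test split) are reported `NA` and excluded from means with an exclusion
count; silently coding them as zero would bias balanced accuracy downward.
A failed fit on one cell is recorded and skipped, never averaged. The
boosted-trees method is a thin adapter over the xgboost library
(`binary:logistic`, 50 rounds, depth 3, learning rate 0.3, single-threaded;
recorded in the result's config attribute), kept because the benchmark's
purpose is comparison against a strong off-the-shelf baseline.

## The synthetic generator

Real screening databases cannot ship with a package, so `synthetic_config()` /
`generate_assay_data()` / `generate_raw_bundle()` emulate their structure:
per-assay active fractions uniform in $[0.05, 0.30]$; continuous descriptors
uniform on $[0,1]$; fingerprints Bernoulli with prevalences uniform in
$[0.05, 0.5]$; labels from a logistic model on `n_informative = 8` randomly
chosen descriptors with coefficients $\pm 2$ (signs random) and an intercept
calibrated by root finding so the expected positive rate equals the target —
with zero effect size the calibration is exact, which is how the generator
itself is tested against exact binomial intervals. The raw-matrix generator
maps actives to log-uniform AC50s in $[0.001, 100]$ (the magnitudes are
arbitrary; only the sentinel matters downstream), inactives to the sentinel,
and masks cells missing independently at the configured rate. Defaults are
404 compounds, 37 assays, 74 continuous descriptors and a 200-column
fingerprint block — the last is a desk-scale stand-in for the thousands of
fingerprint bits real panels carry, chosen so the full pipeline runs in
seconds. Effect size 2 makes assays learnable but imperfect, mirroring the
60–69% balanced-accuracy regime typical of this problem.

What the generator does **not** emulate: real chemical structure
(descriptors are independent, where real descriptors are strongly
correlated), assay cross-correlation, and heavy-tailed descriptor
distributions. Passing benchmarks on synthetic assays therefore demonstrates
that the estimators and the harness are correct and that augmentation moves
sensitivity/specificity in the expected directions — not that any particular
accuracy level will transfer to a real screening database.

## Study conditions used by the checks

The test suite and `scripts/acceptance.R` run at fixed problem sizes chosen
once: 20 random stable networks of 2–4 cells at simulation horizon $10^5$;
the 4-point AND table and 40/60-point separable blobs for learning sanity; a
90/10 set for SMOTE; 7×7 masks for the submatrix comparison; and a benchmark
of 10 assays, 400 compounds, 30 descriptors (10 continuous + 20 fingerprint,
5 informative), 10 split repeats, all three methods, both conditions. On the
benchmark we verify the direction of the augmentation effect — mean test
sensitivity strictly up, mean test specificity strictly down, for every
method — rather than any absolute accuracy, because magnitudes are
data-dependent.

## Known limitations

* The greedy submatrix heuristic has no optimality guarantee; the 60% figure
  is an empirical floor on small masks, not a bound.
* Recurrent RNN training costs one linear solve per sample per epoch; for
  descriptor tables with thousands of columns the MLRNN (fixed projection)
  is the practical choice.
* The xgboost adapter exposes a deliberately small parameter surface; users
  wanting tuned trees should call the library directly.
* SMOTE interpolates in the full mixed continuous/binary descriptor space;
  distance is Euclidean and unweighted, so descriptor scaling (curation's
  normalization) matters.
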
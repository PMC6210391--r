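#' Configuration of the ToxCast-like synthetic generator
#'
#' Describes the study conditions the generator emulates: a
#' compounds-by-assays AC50 matrix with missingness and a mixed
#' binary/continuous descriptor block whose per-assay active fractions lie
#' in the 5-30% range typical of curated in vitro screening panels. The
#' defaults mirror the curated screening matrix the package targets: 404
#' compounds, 37 assays, 74 continuous physico-chemical descriptors, and a
#' desk-scale block of 200 binary fingerprints.
#'
#' @param n_compounds,n_assays,n_physchem,n_fingerprints Table dimensions.
#' @param active_frac Per-assay expected active fraction; `NULL` (default)
#'   draws one per assay from uniform(0.05, 0.30); a scalar or length-
#'   `n_assays` vector fixes them.
#' @param n_informative Number of descriptors carrying signal per assay.
#' @param effect_size Log-odds coefficient magnitude of informative
#'   descriptors (signs random).
#' @param missing_frac Probability an AC50 cell is masked missing.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 404, n_assays = 37,
                             n_physchem = 74, n_fingerprints = 200,
                             active_frac = NULL, n_informative = 8,
                             effect_size = 2, missing_frac = 0.15,
                             seed = 1) {
  stopifnot(n_compounds >= 2, n_assays >= 1, n_physchem >= 0,
            n_fingerprints >= 0, n_physchem + n_fingerprints >= 1,
            n_informative >= 0,
            n_informative <= n_physchem + n_fingerprints,
            effect_size >= 0, missing_frac >= 0, missing_frac < 1)
  if (!is.null(active_frac)) {
    active_frac <- rep_len(as.double(active_frac), n_assays)
    stopifnot(all(active_frac >= 0), all(active_frac < 1))
  }
  structure(list(n_compounds = n_compounds, n_assays = n_assays,
                 n_physchem = n_physchem, n_fingerprints = n_fingerprints,
                 active_frac = active_frac, n_informative = n_informative,
                 effect_size = effect_size, missing_frac = missing_frac,
                 seed = seed),
            class = "synthetic_config")
}

# Calibrate the logistic intercept so the expected positive rate is pi.
calibrate_intercept <- function(eta, pi) {
  f <- function(b0) mean(plogis(b0 + eta)) - pi
  lo <- -60
  hi <- 60
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf("intercept calibration failed for active fraction %.3f", pi),
         call. = FALSE)
  }
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Generate a descriptor table with planted per-assay signal
#'
#' Fingerprints are Bernoulli with per-feature prevalence drawn from
#' uniform(0.05, 0.5); continuous descriptors are uniform(0, 1). For each
#' assay, `n_informative` randomly chosen descriptors receive logistic
#' coefficients of magnitude `effect_size` with random signs, the intercept
#' is calibrated by root finding so the expected positive rate equals the
#' configured active fraction, and labels are drawn from the resulting
#' Bernoulli probabilities. Everything is determined by the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A `gnetox_dataset` (see [curate()]) whose `truth` element records
#'   the per-assay informative descriptors, coefficients, intercept and
#'   target active fraction.
#' @export
generate_assay_data <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed_(cfg$seed, {
    n <- cfg$n_compounds
    ids <- sprintf("C%04d", seq_len(n))
    pc <- matrix(runif(n * cfg$n_physchem), n)
    colnames(pc) <- sprintf("pc_%03d", seq_len(cfg$n_physchem))
    prev <- runif(cfg$n_fingerprints, 0.05, 0.5)
    fp <- matrix(0L, n, cfg$n_fingerprints)
    for (j in seq_len(cfg$n_fingerprints)) fp[, j] <- rbinom(n, 1, prev[j])
    if (cfg$n_fingerprints > 0) {
      colnames(fp) <- sprintf("fp_%03d", seq_len(cfg$n_fingerprints))
    }
    xx <- cbind(pc, fp)
    pis <- cfg$active_frac %||% runif(cfg$n_assays, 0.05, 0.30)
    truth <- vector("list", cfg$n_assays)
    lab <- matrix(0L, n, cfg$n_assays)
    colnames(lab) <- sprintf("assay_%02d", seq_len(cfg$n_assays))
    for (a in seq_len(cfg$n_assays)) {
      pi_a <- pis[a]
      if (pi_a == 0) {
        truth[[a]] <- list(informative = integer(), coef = numeric(),
                           intercept = -Inf, pi = 0)
        next
      }
      inf_idx <- sample(ncol(xx), cfg$n_informative)
      coef <- cfg$effect_size * sample(c(-1, 1), cfg$n_informative,
                                       replace = TRUE)
      eta <- as.numeric(xx[, inf_idx, drop = FALSE] %*% coef)
      b0 <- calibrate_intercept(eta, pi_a)
      p <- plogis(b0 + eta)
      lab[, a] <- rbinom(n, 1, p)
      truth[[a]] <- list(informative = inf_idx, coef = coef,
                         intercept = b0, pi = pi_a, prob = p)
    }
    names(truth) <- colnames(lab)
    features <- tibble::as_tibble(as.data.frame(xx))
    features <- tibble::add_column(features, compound_id = ids, .before = 1)
    labels <- tibble::as_tibble(as.data.frame(lab))
    labels <- tibble::add_column(labels, compound_id = ids, .before = 1)
    structure(
      list(features = features, labels = labels,
           physchem_cols = colnames(pc), fingerprint_cols = colnames(fp),
           truth = truth, config = cfg,
           log = list(order = "synthetic")),
      class = c("synthetic_assay_data", "gnetox_dataset")
    )
  })
}

#' Generate a raw AC50 matrix with missingness
#'
#' Builds the incomplete compounds-by-assays AC50 table upstream of
#' curation: per-assay activity labels are planted with the same logistic
#' machinery as [generate_assay_data()], active cells receive AC50 values
#' log-uniform in `[0.001, 100]`, inactive cells the 1,000,000 sentinel, and
#' each cell is masked missing independently with probability
#' `missing_frac`.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble (`compound_id` + one column per assay, `NA` = missing)
#'   with attribute `planted_labels` — the complete binary label table
#'   before masking.
#' @seealso [generate_raw_bundle()] for the full three-table input of
#'   [curate()].
#' @export
generate_raw_matrix <- function(cfg) {
  generate_raw_bundle(cfg)$ac50
}

#' @rdname generate_raw_matrix
#' @return `generate_raw_bundle()` returns a list with `ac50`, `physchem`
#'   (un-normalized continuous descriptors), `fingerprints`, and `truth`
#'   (the generating `gnetox_dataset`).
#' @export
generate_raw_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ds <- generate_assay_data(cfg)
  with_seed_(cfg$seed + 1L, {
    lab <- as.matrix(ds$labels[, -1, drop = FALSE])
    n <- nrow(lab)
    ac50 <- matrix(1e6, n, ncol(lab), dimnames = list(NULL, colnames(lab)))
    n_active <- sum(lab == 1)
    ac50[lab == 1] <- 10^runif(n_active, -3, 2)
    mask <- matrix(runif(length(ac50)) < cfg$missing_frac, n)
    ac50_masked <- ac50
    ac50_masked[mask] <- NA_real_
    ac50_tbl <- tibble::as_tibble(as.data.frame(ac50_masked))
    ac50_tbl <- tibble::add_column(ac50_tbl,
                                   compound_id = ds$features$compound_id,
                                   .before = 1)
    attr(ac50_tbl, "planted_labels") <- ds$labels
    # raw physchem: per-column affine rescale so curation has real work to do
    pc <- as.matrix(ds$features[, ds$physchem_cols, drop = FALSE])
    scale <- runif(ncol(pc), 0.5, 20)
    offset <- runif(ncol(pc), -5, 5)
    pc_raw <- sweep(sweep(pc, 2, scale, "*"), 2, offset, "+")
    pc_tbl <- tibble::as_tibble(as.data.frame(pc_raw))
    pc_tbl <- tibble::add_column(pc_tbl,
                                 compound_id = ds$features$compound_id,
                                 .before = 1)
    fp_tbl <- ds$features[, c("compound_id", ds$fingerprint_cols)]
    list(ac50 = ac50_tbl, physchem = pc_tbl, fingerprints = fp_tbl,
         truth = ds)
  })
}
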
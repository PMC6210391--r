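test_that("the generator is a pure function of its configuration and seed", {
  cfg <- synthetic_config(n_compounds = 50, n_assays = 3, n_physchem = 4,
                          n_fingerprints = 8, n_informative = 3,
                          missing_frac = 0.1, seed = 13)
  expect_identical(generate_assay_data(cfg), generate_assay_data(cfg))
  expect_identical(generate_raw_matrix(cfg), generate_raw_matrix(cfg))
  cfg2 <- synthetic_config(n_compounds = 50, n_assays = 3, n_physchem = 4,
                           n_fingerprints = 8, n_informative = 3,
                           missing_frac = 0.1, seed = 14)
  expect_false(identical(generate_assay_data(cfg), generate_assay_data(cfg2)))
})

test_that("a zero active fraction yields all-inactive labels", {
  cfg <- synthetic_config(n_compounds = 30, n_assays = 2, n_physchem = 3,
                          n_fingerprints = 0, n_informative = 2,
                          active_frac = 0, missing_frac = 0, seed = 1)
  ds <- generate_assay_data(cfg)
  expect_true(all(as.matrix(ds$labels[, -1]) == 0))
})

test_that("the calibrated intercept hits the target positive rate", {
  # with zero effect size the positive rate is exactly the target in
  # expectation: check the empirical fraction against the exact binomial
  # 99% interval
  n <- 2000
  cfg <- synthetic_config(n_compounds = n, n_assays = 1, n_physchem = 5,
                          n_fingerprints = 5, n_informative = 4,
                          effect_size = 0, active_frac = 0.12,
                          missing_frac = 0, seed = 21)
  ds <- generate_assay_data(cfg)
  k <- sum(ds$labels[[2]])
  ci <- qbinom(c(0.005, 0.995), n, 0.12)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  # with signal, the realized rate still tracks the target
  cfg2 <- synthetic_config(n_compounds = n, n_assays = 1, n_physchem = 5,
                           n_fingerprints = 5, n_informative = 4,
                           effect_size = 2, active_frac = 0.12,
                           missing_frac = 0, seed = 22)
  k2 <- sum(generate_assay_data(cfg2)$labels[[2]])
  expect_gte(k2, qbinom(0.0005, n, 0.12 * 0.7))
  expect_lte(k2, qbinom(0.9995, n, 0.12 * 1.4))
})

test_that("informative descriptors carry more label association than noise", {
  cfg <- synthetic_config(n_compounds = 5000, n_assays = 1, n_physchem = 10,
                          n_fingerprints = 10, n_informative = 4,
                          effect_size = 2, active_frac = 0.2,
                          missing_frac = 0, seed = 23)
  ds <- generate_assay_data(cfg)
  x <- as.matrix(ds$features[, -1])
  y <- ds$labels[[2]]
  assoc <- abs(apply(x, 2, function(v) suppressWarnings(cor(v, y))))
  inf <- ds$truth[[1]]$informative
  noise_median <- median(assoc[-inf])
  expect_true(all(assoc[inf] > noise_median))
})

test_that("the raw matrix plants sentinels, missingness and recoverable labels", {
  n <- 100
  cfg <- synthetic_config(n_compounds = n, n_assays = 100, n_physchem = 3,
                          n_fingerprints = 0, n_informative = 2,
                          missing_frac = 0.2, seed = 31)
  raw <- generate_raw_matrix(cfg)
  cells <- as.matrix(raw[, -1])
  n_cells <- length(cells)  # 10,000 cells
  n_missing <- sum(is.na(cells))
  ci <- qbinom(c(0.005, 0.995), n_cells, 0.2)
  expect_gte(n_missing, ci[1])
  expect_lte(n_missing, ci[2])
  # unmasked cells binarize back to the planted labels
  planted <- as.matrix(attr(raw, "planted_labels")[, -1])
  obs <- !is.na(cells)
  expect_identical(binarize_activity(cells[obs]), unname(planted[obs]))
  # active AC50s live in the configured log-uniform range, inactives at 1e6
  act <- cells[obs & planted == 1]
  expect_true(all(act >= 0.001 & act <= 100))
  expect_true(all(cells[obs & planted == 0] == 1e6))
  # missing_frac = 0 gives a complete matrix that extraction keeps whole
  cfg0 <- synthetic_config(n_compounds = 20, n_assays = 4, n_physchem = 3,
                           n_fingerprints = 0, n_informative = 2,
                           missing_frac = 0, seed = 32)
  raw0 <- generate_raw_matrix(cfg0)
  out0 <- extract_complete_submatrix(raw0)
  expect_equal(as.data.frame(out0), as.data.frame(raw0), ignore_attr = TRUE)
})

test_that("curation of a generated bundle keeps active fractions in range", {
  cfg <- synthetic_config(n_compounds = 300, n_assays = 8, n_physchem = 6,
                          n_fingerprints = 10, n_informative = 3,
                          missing_frac = 0.05, seed = 33)
  b <- generate_raw_bundle(cfg)
  ds <- curate(b$ac50, b$physchem, b$fingerprints)
  fr <- colMeans(as.matrix(ds$labels[, -1]))
  expect_true(all(fr >= 0.05))   # guaranteed by the assay filter
  expect_true(all(fr <= 0.40))   # configured 5-30% range + sampling noise
})
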
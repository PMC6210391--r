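test_that("split instances partition the data and are reproducible", {
  ss <- make_splits(40, r_splits = 8, test_frac = 0.3, seed = 2)
  for (s in ss$splits) {
    expect_setequal(c(s$train, s$test), 1:40)
    expect_length(intersect(s$train, s$test), 0)
  }
  expect_identical(make_splits(40, 8, 0.3, seed = 2)$splits, ss$splits)
  expect_false(identical(make_splits(40, 8, 0.3, seed = 3)$splits, ss$splits))
})

test_that("stratified splitting hits the exact test size with both classes", {
  y <- rep(c(0L, 1L), c(355, 49))  # ~12% actives, n = 404
  ss <- make_splits(404, r_splits = 50, test_frac = 0.25, seed = 4,
                    stratify = y)
  for (s in ss$splits) {
    expect_length(s$test, 101)  # round(404 * 0.25)
    expect_true(all(c(0, 1) %in% y[s$test]))
    expect_true(all(c(0, 1) %in% y[s$train]))
  }
  expect_error(make_splits(10, 5, 0.25, stratify = rep(c(0L, 1L), c(9, 1))),
               "infeasible")
})

test_that("metrics match the textbook formulas and a brute-force tally", {
  y_true <- rep(c(1, 0), c(4, 10))
  y_pred <- c(1, 1, 1, 0, rep(1, 5), rep(0, 5))
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$tn, 5); expect_equal(m$fp, 5)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$ba, 0.625)
  expect_equal(compute_metrics(y_true, y_true)$ba, 1)
  set.seed(9)
  for (rep in 1:10) {
    yt <- rbinom(30, 1, 0.3); yp <- rbinom(30, 1, 0.5)
    m <- compute_metrics(yt, yp)
    tal <- tally_confusion(yt, yp)
    expect_equal(unlist(m[c("tp", "fp", "tn", "fn")]), tal,
                 ignore_attr = TRUE)
    expect_equal(m$tp + m$fp + m$tn + m$fn, 30)
  }
  expect_error(compute_metrics(c(0, 1), c(1)), "differ")
  # undefined metric propagates as NA, never silently 0
  m0 <- compute_metrics(rep(0, 5), rep(0, 5))
  expect_true(is.na(m0$sensitivity))
  expect_true(is.na(m0$ba))
})

test_that("the majority baseline scores BA 0.5 on unbalanced assays", {
  cfg <- synthetic_config(n_compounds = 60, n_assays = 1, n_physchem = 4,
                          n_fingerprints = 0, n_informative = 2,
                          active_frac = 0.2, missing_frac = 0, seed = 5)
  ds <- generate_assay_data(cfg)
  bench <- run_benchmark(ds, methods = "majority", r_splits = 4, seed = 3)
  expect_true(all(bench$sensitivity == 0))
  expect_true(all(bench$specificity == 1))
  expect_true(all(bench$ba == 0.5))
  # confusion counts always sum to the test-set size
  expect_true(all(bench$tp + bench$fp + bench$tn + bench$fn == 15))
})

test_that("aggregation is the unweighted mean over splits, excluding failures", {
  cfg <- synthetic_config(n_compounds = 60, n_assays = 2, n_physchem = 4,
                          n_fingerprints = 0, n_informative = 2,
                          active_frac = 0.25, missing_frac = 0, seed = 6)
  ds <- generate_assay_data(cfg)
  bench <- run_benchmark(ds, methods = "majority", r_splits = 5, seed = 2)
  summ <- summarise_benchmark(bench)
  for (i in seq_len(nrow(summ))) {
    sub <- bench[bench$assay == summ$assay[i] & !bench$failed, ]
    expect_equal(summ$ba[i], mean(sub$ba, na.rm = TRUE))
  }
  # a failed cell is excluded, not averaged as zero
  fake <- bench
  fake$failed[1] <- TRUE
  fake$ba[1] <- NA
  s2 <- summarise_benchmark(fake)
  sub <- fake[fake$assay == fake$assay[1] & !fake$failed, ]
  expect_equal(s2$ba[s2$assay == fake$assay[1]], mean(sub$ba))
  expect_equal(s2$n_excluded[s2$assay == fake$assay[1]], 1)
})

test_that("unknown methods and empty method lists are rejected", {
  cfg <- synthetic_config(n_compounds = 40, n_assays = 1, n_physchem = 3,
                          n_fingerprints = 0, n_informative = 1,
                          active_frac = 0.3, missing_frac = 0, seed = 7)
  ds <- generate_assay_data(cfg)
  expect_error(run_benchmark(ds, methods = "svm"), "no adapter")
  expect_error(run_benchmark(ds, methods = character()), "non-empty")
})

test_that("paired conditions share byte-identical test partitions", {
  cfg <- synthetic_config(n_compounds = 80, n_assays = 2, n_physchem = 4,
                          n_fingerprints = 6, n_informative = 3,
                          active_frac = 0.2, missing_frac = 0, seed = 8)
  ds <- generate_assay_data(cfg)
  both <- compare_augmentation(ds, methods = "majority", r_splits = 3,
                               seed = 5)
  expect_identical(attr(both, "splits_unbalanced"),
                   attr(both, "splits_augmented"))
  expect_setequal(unique(both$condition), c("unbalanced", "augmented"))
})
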
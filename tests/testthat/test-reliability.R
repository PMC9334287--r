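test_that("dice counts pixel overlap", {
  a <- rect_mask(label = 1L)
  expect_equal(dice(a, a, 1L), 1)
  b <- rect_mask(label = 1L, x0 = 131, x1 = 159, y0 = 80, y1 = 100)
  expect_equal(dice(a, b, 1L), 0)
  # |A| = |B| = 100, overlap 80
  a2 <- matrix(0L, 50, 50); a2[11:20, 11:20] <- 1L
  b2 <- matrix(0L, 50, 50); b2[11:20, 13:22] <- 1L
  expect_equal(dice(a2, b2, 1L), 0.8)
  expect_equal(dice(a2, b2, 3L), 1)  # absent from both
  expect_error(dice(a2, matrix(0L, 10, 10), 1L), "shape")
})

test_that("dice is symmetric, bounded, and 1 only on equality", {
  set.seed(5)
  for (i in 1:20) {
    a <- matrix(as.integer(runif(400) < 0.4), 20, 20)
    b <- matrix(as.integer(runif(400) < 0.4), 20, 20)
    d <- dice(a, b, 1L)
    expect_identical(d, dice(b, a, 1L))
    expect_gte(d, 0); expect_lte(d, 1)
    if (d == 1) expect_identical(a == 1L, b == 1L)
  }
})

test_that("one-way ICC matches the explicit-sums oracle and its exact CI", {
  x <- ratings_6x3()[, 1:2]
  r <- icc_oneway_single(x)
  expect_equal(r$estimate, oracle_icc(x)$icc1, tolerance = 1e-10)
  # frozen high-precision values, cross-checked against an independent
  # implementation of the exact F interval
  expect_equal(r$estimate, 0.7971014493, tolerance = 1e-9)
  expect_equal(r$ci_low, 0.1933064453, tolerance = 1e-9)
  expect_equal(r$ci_high, 0.9681541351, tolerance = 1e-9)

  r3 <- icc_oneway_single(ratings_6x3())
  expect_equal(r3$estimate, 0.8461538462, tolerance = 1e-9)
  expect_equal(r3$ci_low, 0.5382771094, tolerance = 1e-9)
  expect_equal(r3$ci_high, 0.9741779133, tolerance = 1e-9)

  # identical columns, subject variance > 0 -> perfect agreement
  same <- cbind(c(1, 5, 9, 3), c(1, 5, 9, 3))
  expect_warning(ri <- icc_oneway_single(same), "degenerate|variance")
  expect_equal(ri$estimate, 1)

  flat <- matrix(4, 5, 2)
  expect_warning(rf <- icc_oneway_single(flat), "zero-variance")
  expect_equal(rf$estimate, 1)
})

test_that("two-way random agreement ICC matches oracle and penalizes offsets", {
  x <- ratings_6x3()
  r <- icc_twoway_random_single(x)
  expect_equal(r$estimate, oracle_icc(x)$icc_a1, tolerance = 1e-10)
  expect_equal(r$estimate, 0.8449612403, tolerance = 1e-9)
  expect_equal(r$ci_low, 0.5105102265, tolerance = 1e-9)
  expect_equal(r$ci_high, 0.9743604388, tolerance = 1e-9)

  perfect <- cbind(c(2, 7, 4, 9, 6), c(2, 7, 4, 9, 6))
  offset <- perfect; offset[, 2] <- offset[, 2] + 5
  expect_lt(icc_twoway_random_single(offset)$estimate, 1)

  # location and positive-scale invariance
  expect_equal(icc_twoway_random_single(x + 5)$estimate, r$estimate,
               tolerance = 1e-12)
  expect_equal(icc_twoway_random_single(x * 3.7)$estimate, r$estimate,
               tolerance = 1e-12)
})

test_that("both estimators agree with the oracle on random tables", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:20, 1); k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k, sd = runif(1, 0.5, 4)) +
                  rep(rnorm(n, sd = 2), k), n, k)
    o <- oracle_icc(x)
    expect_equal(icc_oneway_single(x)$estimate, o$icc1, tolerance = 1e-10)
    expect_equal(icc_twoway_random_single(x)$estimate, o$icc_a1,
                 tolerance = 1e-10)
  }
})

test_that("paired-bootstrap ICC difference behaves and is seeded", {
  set.seed(31)
  truth <- rnorm(40, sd = 6)
  a <- cbind(truth + rnorm(40, sd = 1), truth + rnorm(40, sd = 1),
             truth + rnorm(40, sd = 1))
  same <- icc_difference(a, a, n_boot = 200, rng_seed = 4)
  expect_equal(same$difference, 0)
  expect_gte(same$ci_low, -1e-12); expect_lte(same$ci_low, 1e-12)
  expect_gt(same$p_value, 0.99)

  noisy <- a; noisy[, 2] <- truth + rnorm(40, sd = 12)
  worse <- icc_difference(a, noisy, n_boot = 400, rng_seed = 4)
  expect_lt(worse$difference, 0)
  expect_lt(worse$ci_high, 0)

  again <- icc_difference(a, noisy, n_boot = 400, rng_seed = 4)
  expect_identical(worse, again)
  expect_error(icc_difference(a, noisy, n_boot = 50), "n_boot")
  expect_error(icc_difference(a, noisy[1:30, ]), "same subjects")
})

test_that("Altman bands use the half-open clinical scale", {
  expect_equal(altman_band(0.955), "very good")
  expect_equal(altman_band(0.81), "very good")
  expect_equal(altman_band(0.80), "good")
  expect_equal(altman_band(0.61), "good")
  expect_equal(altman_band(0.60), "moderate")
  expect_equal(altman_band(0.41), "moderate")
  expect_equal(altman_band(0.05), "fair/poor")
})

test_that("Wald intervals reproduce the reference validation-table cells", {
  # 40/42 sensitivity
  s <- diagnostic_from_counts(tp = 40, fn = 2, tn = 0, fp = 0)
  expect_equal(round(unname(s$sensitivity["estimate"]), 2), 95.24)
  expect_equal(round(unname(s$sensitivity["ci_low"]), 2), 88.80)
  expect_equal(round(unname(s$sensitivity["ci_high"]), 2), 100.00)
  # 42/42: degenerate interval collapses at 100
  s2 <- diagnostic_from_counts(tp = 42, fn = 0, tn = 0, fp = 0)
  expect_equal(unname(s2$sensitivity[c("estimate", "ci_low", "ci_high")]),
               c(100, 100, 100))
  # 41/53 specificity
  s3 <- diagnostic_from_counts(tp = 0, fn = 0, tn = 41, fp = 12)
  expect_equal(round(unname(s3$specificity["estimate"]), 2), 77.36)
  expect_equal(round(unname(s3$specificity["ci_low"]), 2), 66.09)
  expect_equal(round(unname(s3$specificity["ci_high"]), 2), 88.63)
  # 36/42 sensitivity
  s4 <- diagnostic_from_counts(tp = 36, fn = 6, tn = 0, fp = 0)
  expect_equal(round(unname(s4$sensitivity["ci_low"]), 2), 75.13)
  expect_equal(round(unname(s4$sensitivity["ci_high"]), 2), 96.30)

  # vector interface consistent with counts
  pred <- c(rep(TRUE, 40), rep(FALSE, 2))
  truth <- rep(TRUE, 42)
  sv <- diagnostic_metrics(pred, truth)
  expect_equal(sv$sensitivity, s$sensitivity)
  expect_true(is.na(sv$specificity["estimate"]))  # no negatives present
  expect_error(diagnostic_metrics(c(TRUE, FALSE), TRUE), "length")
})

test_that("reader pooling micro-averages confusion counts", {
  sens_counts <- c(40, 36, 38)
  readers <- lapply(sens_counts, function(tp)
    diagnostic_from_counts(tp = tp, fn = 42 - tp, tn = 0, fp = 0))
  pooled <- pool_readers(readers)
  expect_equal(round(unname(pooled$sensitivity["estimate"]), 2), 90.48)

  spec_counts <- c(41, 51, 44)
  readers2 <- lapply(spec_counts, function(tn)
    diagnostic_from_counts(tp = 0, fn = 0, tn = tn, fp = 53 - tn))
  pooled2 <- pool_readers(readers2)
  expect_equal(round(unname(pooled2$specificity["estimate"]), 2), 85.53)

  one <- diagnostic_from_counts(10, 2, 20, 3)
  expect_equal(pool_readers(list(one)), one)
  expect_error(pool_readers(list()), "empty")
})

test_that("paired bootstrap metric comparison is calibrated and seeded", {
  set.seed(12)
  truth <- rep(c(TRUE, FALSE), each = 100)
  perfect <- truth
  chance <- runif(200) < 0.5
  same <- compare_paired_bootstrap(perfect, perfect, truth, "accuracy",
                                   n_boot = 1000, rng_seed = 2)
  expect_gt(same$p_value, 0.9999)
  diff <- compare_paired_bootstrap(perfect, chance, truth, "accuracy",
                                   n_boot = 1000, rng_seed = 2)
  expect_lt(diff$p_value, 0.01)
  expect_lt(diff$difference, 0)
  again <- compare_paired_bootstrap(perfect, chance, truth, "accuracy",
                                    n_boot = 1000, rng_seed = 2)
  expect_identical(diff, again)
})
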
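test_that("random split is seeded, exhaustive and validated", {
  s <- split_samples(87, 60, 27, seed = 101)
  expect_length(s$train_idx, 60)
  expect_length(s$valid_idx, 27)
  expect_setequal(c(s$train_idx, s$valid_idx), 1:87)
  expect_identical(s, split_samples(87, 60, 27, seed = 101))
  expect_false(identical(s$train_idx,
                         split_samples(87, 60, 27, seed = 102)$train_idx))
  expect_error(split_samples(87, 60, 20), "!=")
  expect_error(split_samples(87, 87, 0), "validation")
})

test_that("two-band OLS recovers a planted affine model exactly", {
  set.seed(7)
  x <- cbind(`516` = runif(30), `724` = runif(30))
  y <- 0.057 - 0.851 * x[, 1] + 0.073 * x[, 2]
  m <- fit_two_band(x, y, standardize = FALSE)
  expect_equal(m$intercept, 0.057, tolerance = 1e-8)
  expect_equal(m$coefficients, c(-0.851, 0.073), tolerance = 1e-8)
  expect_equal(unname(predict(m, x)), unname(y), tolerance = 1e-8)

  # standardization changes coefficients, never predictions
  ms <- fit_two_band(x, y, standardize = TRUE)
  expect_equal(predict(ms, x), predict(m, x), tolerance = 1e-8)
  expect_equal(ms$coefficients_raw, c(-0.851, 0.073), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ms$intercept_raw, 0.057, tolerance = 1e-8)

  # constant response: zero slopes, intercept at the constant
  yc <- rep(5, 30)
  mc <- fit_two_band(x, yc)
  expect_equal(mc$coefficients, c(0, 0), tolerance = 1e-12)
  expect_equal(unname(predict(mc, x)), yc, tolerance = 1e-12)

  expect_error(fit_two_band(cbind(a = x[, 1], b = 2 * x[, 1]), y),
               "collinear")
  expect_error(fit_two_band(x[1:2, ], y[1:2]), "at least 3")
  expect_error(fit_two_band(x[, 1, drop = FALSE], y), "exactly 2")
})

test_that("NIPALS PLS1 hits its two analytic limits", {
  set.seed(8)
  x <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  # full-rank component count -> OLS predictions
  ols <- stats::lm.fit(cbind(1, x), y)
  pls <- fit_pls(x, y, n_components = 5)
  expect_equal(unname(predict(pls, x)), unname(ols$fitted.values),
               tolerance = 1e-6)
  # y proportional to one predictor -> exact with a single component
  y1 <- 3 * x[, 2]
  p1 <- fit_pls(x[, 2, drop = FALSE], y1, 1)
  expect_equal(unname(predict(p1, x[, 2, drop = FALSE])), unname(y1),
               tolerance = 1e-10)

  expect_error(fit_pls(x, y, 6), "outside")
  expect_error(fit_pls(cbind(x, x[, 1]), y, 6), "outside")
  expect_error(fit_pls(cbind(x, const = 1), y, 2), "zero-variance")
})

test_that("component choice by leave-one-out RMSE stays within rank", {
  set.seed(9)
  x <- matrix(rnorm(80), 20, 4)
  y <- x %*% c(1, -2, 0, 0) + rnorm(20, 0, 0.05)
  k <- choose_pls_ncomp(x, y)
  expect_true(k >= 1 && k <= 4)
  m <- fit_pls(x, drop(y), k)
  expect_gt(r_squared(drop(y), predict(m, x)), 0.95)
})

test_that("R^2 and RMSE match their defining formulas", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(r_squared(1:5, rep(3, 5)), 0)        # predicting the mean
  expect_equal(r_squared(1:5, 1:5), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), 0.5774, tolerance = 1e-4)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
  expect_error(r_squared(1:3, 1:2), "equal-length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")

  set.seed(10)
  for (i in 1:100) {
    m <- rnorm(20); p <- m + rnorm(20)
    expect_equal(r_squared(m, p), oracle_r_squared(m, p), tolerance = 1e-12)
    expect_equal(rmse(m, p), oracle_rmse(m, p), tolerance = 1e-12)
  }
})
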
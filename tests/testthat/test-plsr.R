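tbl_from_matrix <- function(X, y, wl = 700 + 3 * seq_len(ncol(X))) {
  colnames(X) <- as.character(wl)
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("S%d", seq_len(nrow(X))),
                                  ssc_ref = y),
                   tibble::as_tibble(X))
}

test_that("constant response yields a degenerate mean model", {
  set.seed(1)
  d <- tbl_from_matrix(matrix(rnorm(30), 10, 3), rep(12, 10))
  fit <- fit_plsr(d)
  expect_true(fit$degenerate)
  expect_equal(fit$n_components, 0L)
  expect_equal(predict(fit, d), rep(12, 10))
})

test_that("full-rank PLSR equals the least-squares oracle", {
  # n = 6 samples, 3 independent wavelengths, all 3 components
  set.seed(2)
  X <- matrix(rnorm(18), 6, 3)
  y <- as.numeric(X %*% c(2, -1, 0.5) + rnorm(6, 0, 0.2))
  d <- tbl_from_matrix(X, y)
  fit <- fit_plsr(d, max_components = 3, cv = "none")
  ols <- lm(y ~ X)                      # normal-equations oracle
  expect_equal(predict(fit, d), unname(fitted(ols)), tolerance = 1e-8)

  # seeded random instances: full-component PLSR == OLS to 1e-8
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12; p <- 4
    X <- matrix(rnorm(n * p), n, p)
    y <- as.numeric(X %*% rnorm(p) + rnorm(n, 0, 0.1))
    d <- tbl_from_matrix(X, y)
    fit <- fit_plsr(d, max_components = p, cv = "none")
    expect_equal(predict(fit, d), unname(fitted(lm(y ~ X))),
                 tolerance = 1e-8)
  }
})

test_that("rank-1 structure is solved by a single CV-selected component", {
  set.seed(3)
  u <- rnorm(20); v <- rnorm(5)
  X <- u %*% t(v)
  y <- 2 * u
  d <- tbl_from_matrix(X, y)
  fit <- fit_plsr(d, max_components = 4)
  expect_equal(fit$n_components, 1L)
  expect_equal(predict(fit, d), y, tolerance = 1e-8)
})

test_that("prediction honours the centering identity and score geometry", {
  set.seed(4)
  X <- matrix(rnorm(80), 20, 4)
  y <- as.numeric(X %*% c(1, 0.5, -1, 0) + rnorm(20, 0, 0.3))
  d <- tbl_from_matrix(X, y)
  fit <- fit_plsr(d, max_components = 3, cv = "loo")
  # training mean spectrum -> training mean response
  mean_row <- matrix(colMeans(X), 1)
  expect_equal(predict(fit, mean_row), mean(y), tolerance = 1e-10)
  # training residuals orthogonal to extracted scores
  resid <- y - predict(fit, d)
  expect_equal(max(abs(crossprod(fit$scores, resid))), 0, tolerance = 1e-8)
  # wavelength mismatch is an error
  expect_error(predict(fit, tbl_from_matrix(X, y, wl = 1:4)), "grid")
})

test_that("CV-selected component count never exceeds the cap", {
  for (seed in 1:4) {
    cfg <- spectra_config(n_samples = 40, seed = seed)
    d2 <- second_derivative(generate_spectra(cfg))
    fit <- fit_plsr(d2, max_components = 7)
    expect_lte(fit$n_components, 7)
    expect_gte(fit$n_components, 1)
  }
})

test_that("prediction statistics follow their definitions", {
  y <- c(10, 11, 12, 13)
  s <- prediction_stats(y, y, 1)
  expect_equal(s$rmsep, 0)
  expect_equal(s$adjusted_r2, 1)
  expect_equal(s$bias_slope, 1)
  expect_equal(s$bias_intercept, 0, tolerance = 1e-12)

  s2 <- prediction_stats(y + 1, y, 1)
  expect_equal(s2$rmsep, 1)

  errs <- c(0.3, -0.4, 0.0, 0.5)
  s3 <- prediction_stats(y + errs, y, 2)
  expect_equal(s3$rmsep, sqrt(mean(errs^2)))
  expect_equal(round(s3$rmsep, 4), 0.3536)

  expect_error(prediction_stats(rep(1, 4), y, 1), "zero variance")
  expect_error(prediction_stats(1:3, 1:4, 1), "lengths differ")
})

test_that("models survive a serialization round trip", {
  cfg <- spectra_config(n_samples = 40, seed = 12)
  d2 <- second_derivative(generate_spectra(cfg))
  fit <- fit_plsr(d2)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsr(fit, path)
  back <- read_plsr(path)
  expect_equal(predict(back, d2), predict(fit, d2), tolerance = 1e-12)
  expect_equal(back$n_components, fit$n_components)
  expect_error(read_plsr(withr::local_tempfile(fileext = ".json",
                                               lines = "{}")), "not an")
})
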
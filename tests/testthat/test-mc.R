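# Reference pool shared by the Monte Carlo tests: moderate size keeps the
# suite fast; scenario-level behaviour is checked at scale in the
# acceptance tests.
mc_pool <- local({
  cfg <- spectra_config(n_samples = 900, seed = 17)
  second_derivative(generate_spectra(cfg))
})

test_that("stratified sampling draws equal parts per year", {
  s <- stratified_sample(mc_pool, 20, seed = 5)
  expect_equal(nrow(s), 60)
  expect_true(all(table(s$year) == 20))
  expect_equal(anyDuplicated(s$sample_id), 0L)
  # determinism
  expect_same_table(s, stratified_sample(mc_pool, 20, seed = 5))
  # exhausted pool errors and names the year
  expect_error(stratified_sample(mc_pool, 1000, seed = 5), "2016")
})

test_that("stratified sampling covers the SSC range", {
  s <- stratified_sample(mc_pool, 40, seed = 6, bins = 4)
  # every within-year SSC quartile of the pool is represented
  for (yr in unique(mc_pool$year)) {
    pool <- mc_pool$ssc_ref[mc_pool$year == yr]
    qs <- quantile(pool, c(0.25, 0.5, 0.75))
    got <- s$ssc_ref[s$year == yr]
    bins <- table(cut(got, c(-Inf, qs, Inf)))
    expect_true(all(bins >= 5))
  }
})

test_that("laboratory noise is unbiased, scaled and seed-sensitive", {
  y <- runif(10000, 5, 14)
  expect_identical(add_lab_noise(y, 0), y)
  z <- add_lab_noise(y, 2, seed = 1)
  expect_equal(sd(z - y), 2, tolerance = 0.06)
  expect_equal(mean(z - y), 0, tolerance = 0.06)
  expect_false(identical(add_lab_noise(y, 2, seed = 1),
                         add_lab_noise(y, 2, seed = 2)))
  expect_error(add_lab_noise(y, -0.1), ">= 0")
})

test_that("noiseless reference data drive RMSEP to the noise floor", {
  quiet <- second_derivative(generate_spectra(
    spectra_config(n_samples = 1200, noise_sd_absorbance = 0, seed = 19)))
  s <- mc_setting("sample_size", n_cal_per_year = 100, reps = 1,
                  n_validation_per_year = 50, seed = 2)
  r <- run_mc_setting(s, quiet)
  expect_lt(r$rmsep[r$group == "all"], 0.05)
})

test_that("scenario runs are reproducible and tidy", {
  s <- mc_setting("sample_size", n_cal_per_year = 40, reps = 3,
                  n_validation_per_year = 30, seed = 4)
  r1 <- run_mc_setting(s, mc_pool)
  r2 <- run_mc_setting(s, mc_pool)
  expect_same_table(r1, r2)
  expect_setequal(unique(r1$rep), 1:3)
  expect_true(all(c("all", "2016", "2017", "2018") %in% r1$group))
  m <- mc_summarise(r1)
  expect_equal(unique(m$reps), 3L)
  expect_true(all(m$sd_rmsep >= 0))
})

test_that("calibration-only perturbation leaves validation untouched", {
  base <- mc_setting("sample_size", n_cal_per_year = 60, reps = 2,
                     n_validation_per_year = 40, seed = 8)
  noisefree <- mc_setting("lab_error", noise_sd = 0, n_cal_per_year = 60,
                          reps = 2, n_validation_per_year = 40, seed = 8)
  noisy <- mc_setting("lab_error", noise_sd = 2, n_cal_per_year = 60,
                      reps = 2, n_validation_per_year = 40, seed = 8)
  # with s = 0 the lab-error scenario reduces exactly to the standard one
  expect_equal(run_mc_setting(noisefree, mc_pool)$rmsep,
               run_mc_setting(base, mc_pool)$rmsep)
  # with s > 0 only the calibration responses (and hence the model) change;
  # the reference pool itself is untouched by value semantics, and RMSEP is
  # still computed against the unperturbed validation truth
  r <- run_mc_setting(noisy, mc_pool)
  expect_true(all(is.finite(r$rmsep)))
  expect_false(isTRUE(all.equal(r$rmsep,
                                run_mc_setting(base, mc_pool)$rmsep)))
})

test_that("ssc-range mode reports per-bin RMSEP", {
  s <- mc_setting("ssc_range", n_cal_per_year = 100, reps = 2,
                  n_validation_per_year = 60, seed = 12)
  r <- run_mc_setting(s, mc_pool)
  bins <- setdiff(unique(r$group), "all")
  expect_gte(length(bins), 4)
  expect_true(all(grepl("\\(", bins)))
})

test_that("transfer mode crosses training sets with validation years", {
  s <- mc_setting("transfer", n_cal_per_year = 60, reps = 2,
                  n_validation_per_year = 30,
                  train_years = list(2016, 2017), seed = 13)
  r <- run_mc_setting(s, mc_pool)
  expect_setequal(unique(r$train), c("2016", "2017"))
  expect_setequal(unique(r$group), c("2016", "2017", "2018"))
  expect_equal(nrow(r), 2 * 2 * 3)
})

test_that("temperature mode groups by scan temperature", {
  s <- mc_setting("temperature", n_cal_per_year = 60, reps = 2,
                  n_validation_per_year = 30, seed = 14)
  r <- run_mc_setting(s, mc_pool)
  expect_true(all(c("T10", "T20", "T30") %in% r$group))
})
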
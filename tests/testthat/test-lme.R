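small_orchard <- generate_orchard(small_orchard_config(seed = 41))

test_that("Model 3 is a plain linear regression", {
  fit <- fit_ssc_lme(small_orchard, model = 3)
  oracle <- lm(ssc ~ wafb + year + sector + crop_load + temperature_trt +
                 calcium + wafb:year + wafb:sector + wafb:crop_load +
                 wafb:temperature_trt + wafb:calcium, data = small_orchard)
  expect_equal(setNames(fit$coefficients$estimate, fit$coefficients$term),
               coef(oracle)[fit$coefficients$term], tolerance = 1e-10)
  expect_equal(fit$aic, AIC(oracle))
  expect_equal(fit$variance_components$sd_tree_intercept, 0)
})

test_that("without true random effects the LME matches least squares", {
  cfg <- small_orchard_config(seed = 43)
  cfg$sd_tree_intercept <- 0; cfg$sd_tree_slope <- 0
  cfg$sd_fruit_intercept <- 0; cfg$sd_fruit_slope <- 0
  data <- generate_orchard(cfg)
  fit1 <- fit_ssc_lme(data, model = 1)
  fit3 <- fit_ssc_lme(data, model = 3)
  expect_true(fit1$singular)          # boundary fit flagged, not rejected
  merged <- merge(fit1$coefficients, fit3$coefficients, by = "term")
  expect_lt(max(abs(merged$estimate.x - merged$estimate.y)), 1e-4)
})

test_that("non-nested fruit-tree mapping is rejected", {
  broken <- small_orchard
  broken$tree_id[1] <- broken$tree_id[nrow(broken)]
  expect_error(fit_ssc_lme(broken, model = 1), "non-nested")
})

test_that("the |t| > 2 significance rule is strict", {
  expect_true(significance_flag(2.1))
  expect_false(significance_flag(-2.0))
  expect_false(significance_flag(0))
  expect_true(significance_flag(-2.0001))
  expect_error(significance_flag(NaN), "finite")
})

test_that("model comparison checks data identity and flags the best fit", {
  f2 <- fit_ssc_lme(small_orchard, model = 2)
  f3 <- fit_ssc_lme(small_orchard, model = 3)
  cmp <- model_compare(f2, f3)
  expect_equal(nrow(cmp), 2)
  expect_equal(sum(cmp$best_aic), 1L)
  # identical fits give identical rows
  cmp2 <- model_compare(f3, fit_ssc_lme(small_orchard, model = 3))
  expect_equal(cmp2$aic[1], cmp2$aic[2])
  expect_equal(cmp2$rmse[1], cmp2$rmse[2])
  other <- generate_orchard(small_orchard_config(seed = 77))
  expect_error(model_compare(f2, fit_ssc_lme(other, model = 2)),
               "differing data")
})

test_that("effect tables are affine in DAFB with zero baseline offsets", {
  em <- effect_model(intercept = 4, week = 0.3,
                     effects = list(sector = c(middle = 0.1, top = 0.4)),
                     interactions = list(sector = c(middle = 0.01,
                                                    top = 0.02)))
  tab <- evaluate_effects(em, dafb = seq(40, 140, 20), digits = 10)
  # unspecified factors stay identically zero
  expect_true(all(tab$light == 0) && all(tab$cold == 0))
  # exact collinearity of every column across rows
  for (col in setdiff(names(tab), "dafb")) {
    fitline <- lm(tab[[col]] ~ tab$dafb)
    expect_lt(max(abs(residuals(fitline))), 1e-9)
  }
  expect_equal(tab$top, 0.4 + 0.02 * tab$dafb / 7, tolerance = 1e-9)

  # all effects zero -> offsets identically zero
  em0 <- effect_model(4, 0.3)
  tab0 <- evaluate_effects(em0)
  expect_true(all(as.matrix(tab0[, -(1:2)]) == 0))
})

test_that("effect tables from a fitted model reproduce the generator", {
  cfg <- orchard_config(
    years = data.frame(year = 2016, n_trees = 60, n_fruit = 300),
    weeks = 6:20,
    sd_tree_intercept = 0.05, sd_tree_slope = 0.005,
    sd_fruit_intercept = 0.05, sd_fruit_slope = 0.005,
    sd_residual = 0.1, seed = 47)
  fit <- fit_ssc_lme(generate_orchard(cfg), model = 1)
  tab <- evaluate_effects(fit, dafb = c(40, 140))
  truth_top <- 0.39 + 0.0252 * c(40, 140) / 7
  expect_equal(tab$top, truth_top, tolerance = 0.12)
})

test_that("effect ranges span baseline and extreme levels", {
  em <- effect_model(4, 0.3,
                     effects = list(sector = c(middle = 0.43, top = 0.89),
                                    crop_load = c(light = 0.25,
                                                  heavy = -0.17)))
  tab <- evaluate_effects(em, dafb = 140)
  expect_equal(effect_range(tab, "sector", 140), 0.89)
  expect_equal(effect_range(tab, "crop_load", 140), 0.42)
  expect_equal(effect_range(tab, "temperature_trt", 140), 0)
  expect_error(effect_range(tab, "calcium", 140), "unknown factor")
  expect_error(effect_range(tab, "sector", 60), "one table row")
})

test_that("sensitivity refits degrade precision as designed", {
  data <- generate_orchard(orchard_config(
    years = data.frame(year = c(2016, 2017), n_trees = c(20, 20),
                       n_fruit = c(80, 80)),
    weeks = 7:16, seed = 51))
  sens <- sensitivity_models(data, n_trees = 16, n_fruit = 60,
                             noise_sd = 1.0, seed = 3)
  full <- sens$multi_year$coefficients
  for (m in c("A", "B")) {
    merged <- merge(full, sens[[m]]$coefficients, by = "term",
                    suffixes = c("_full", "_sub"))
    expect_true(all(merged$std_error_sub > merged$std_error_full))
  }
  # Model C: residual variance inflated by ~ noise_sd^2
  v_full <- sens$multi_year$variance_components$sd_residual^2
  v_c <- sens$C$variance_components$sd_residual^2
  expect_equal(v_c - v_full, 1.0, tolerance = 0.15)
  # reproducibility of the subsampling
  sens2 <- sensitivity_models(data, n_trees = 16, n_fruit = 60,
                              noise_sd = 1.0, seed = 3)
  expect_equal(sens2$A$coefficients$estimate, sens$A$coefficients$estimate)
  expect_error(sensitivity_models(data, n_trees = 1000), "not enough trees")
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_ssc_lme(small_orchard, model = 2)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "t_value",
                    "significant") %in% names(td)))
  expect_equal(td$t_value, td$estimate / td$std_error)
  g <- glance(fit)
  expect_equal(g$n_obs, nrow(small_orchard))
  expect_true(g$sd_residual > 0)
})
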
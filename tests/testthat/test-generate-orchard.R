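test_that("degenerate generative model collapses to the population line", {
  orch <- generate_orchard(deterministic_orchard_config(intercept = 4,
                                                        slope = 0.3))
  expect_equal(orch$ssc, 4 + 0.3 * orch$wafb, tolerance = 1e-12)
  expect_equal(orch$dafb, 7L * orch$wafb)
})

test_that("variance decomposes as configured", {
  cfg <- orchard_config(
    years = data.frame(year = 2016, n_trees = 10, n_fruit = 400),
    weeks = 8:15,
    effects = list(intercept = 4, week = 0.3, year = c(), sector = c(),
                   crop_load = c(), temperature_trt = c(), calcium = c()),
    interactions = list(),
    sd_tree_intercept = 0, sd_tree_slope = 0,
    sd_fruit_intercept = 0.5, sd_fruit_slope = 0,
    sd_residual = 0, seed = 21)
  orch <- generate_orchard(cfg)
  # within-fruit trajectories are exact lines
  by_fruit <- split(orch, orch$fruit_id)
  slopes <- vapply(by_fruit, function(d) {
    coef(lm(ssc ~ wafb, data = d))[["wafb"]]
  }, numeric(1))
  intercepts <- vapply(by_fruit, function(d) {
    coef(lm(ssc ~ wafb, data = d))[["(Intercept)"]]
  }, numeric(1))
  expect_equal(unname(slopes), rep(0.3, length(slopes)), tolerance = 1e-10)
  # between-fruit intercept variance ~ 0.25 (400 fruit draws)
  expect_equal(var(intercepts), 0.25, tolerance = 0.2 * 0.25 + 0.02)

  # residual-only config conserves sigma_e^2
  cfg2 <- deterministic_orchard_config(sd_residual = 0.3)
  cfg2$seed <- 22
  orch2 <- generate_orchard(cfg2)
  resid <- orch2$ssc - (4 + 0.3 * orch2$wafb)
  expect_equal(sd(resid), 0.3, tolerance = 0.1)
})

test_that("per-fruit OLS slopes recover the population slope", {
  cfg <- orchard_config(seed = 31)
  cfg$interactions <- list()        # pure beta1 = 0.31 slope structure
  orch <- generate_orchard(cfg)
  slopes <- vapply(split(orch, orch$fruit_id), function(d) {
    coef(lm(ssc ~ wafb, data = d))[["wafb"]]
  }, numeric(1))
  expect_equal(mean(slopes), 0.31, tolerance = 0.02)
  expect_equal(length(unique(orch$tree_id)), 237)
  expect_equal(length(unique(orch$fruit_id)), 1274)
})

test_that("orchard generation is deterministic and respects nesting", {
  cfg <- small_orchard_config(seed = 7)
  a <- generate_orchard(cfg)
  expect_same_table(a, generate_orchard(cfg))
  trees_per_fruit <- tapply(a$tree_id, a$fruit_id,
                            function(x) length(unique(x)))
  expect_true(all(trees_per_fruit == 1))
  expect_true(all(is.finite(a$ssc)))
  # treatments are constant within tree
  for (fac in c("crop_load", "temperature_trt", "calcium")) {
    expect_true(all(tapply(a[[fac]], a$tree_id,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("dropout produces unbalanced but prefix-complete trajectories", {
  cfg <- small_orchard_config(seed = 9, dropout = 0.15)
  orch <- generate_orchard(cfg)
  full <- length(cfg$weeks)
  counts <- table(orch$fruit_id)
  expect_lt(mean(counts), full)
  # surviving scans are always the leading part of the schedule
  ok <- vapply(split(orch$wafb, orch$fruit_id), function(w) {
    identical(sort(w), cfg$weeks[seq_along(w)])
  }, logical(1))
  expect_true(all(ok))
})

test_that("invalid orchard configurations are rejected", {
  expect_error(orchard_config(weeks = integer(0)), "non-empty")
  expect_error(orchard_config(sd_residual = -1), ">= 0")
  expect_error(orchard_config(years = data.frame(year = 2016, n_trees = 0,
                                                 n_fruit = 5)))
})
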
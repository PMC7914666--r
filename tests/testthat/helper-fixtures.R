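# Shared fixtures and independent oracles, built in code at test time.

# Small aligned grid containing the 729-975 nm window exactly.
aligned_spectra_config <- function(...) {
  spectra_config(wavelength_start = 309, wavelength_stop = 1101, ...)
}

# Orchard config at reduced scale for fast mixed-model tests.
small_orchard_config <- function(..., seed = 1) {
  orchard_config(
    years = data.frame(year = c(2016, 2017), n_trees = c(12, 12),
                       n_fruit = c(48, 48)),
    weeks = 8:15, seed = seed, ...)
}

# A config whose generative model is a pure fixed-effect line.
deterministic_orchard_config <- function(intercept = 4, slope = 0.3,
                                         sd_residual = 0, ...) {
  orchard_config(
    years = data.frame(year = 2016, n_trees = 6, n_fruit = 18),
    weeks = 7:14,
    effects = list(intercept = intercept, week = slope,
                   year = c(), sector = c(), crop_load = c(),
                   temperature_trt = c(), calcium = c()),
    interactions = list(),
    sd_tree_intercept = 0, sd_tree_slope = 0,
    sd_fruit_intercept = 0, sd_fruit_slope = 0,
    sd_residual = sd_residual, seed = 1, ...)
}

# Exhaustive Mann-Whitney oracle: distribution of U over all assignments of
# the pooled values to the two groups, two-sided p as 2*min(tail) capped at 1.
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  splits <- utils::combn(n, length(a))
  u_of <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  u_all <- apply(splits, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  u_obs <- u_of(a, b)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

expect_same_table <- function(x, y) {
  expect_equal(as.data.frame(x), as.data.frame(y))
}
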
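#' Configuration for the synthetic longitudinal orchard generator
#'
#' Describes the generative process behind [generate_orchard()]: a linear
#' mixed-effect trajectory for each fruit,
#' `ssc = (b0 + year + main effects + u_tree0 + u_fruit0) +
#' (b1 + interactions + u_tree1 + u_fruit1) * wafb + e`,
#' with independent Gaussian random intercepts and slopes at the tree and the
#' fruit level (fruit nested in trees) and an observation-level residual.
#' Time is measured in weeks after full bloom (WAFB); days after full bloom
#' are `dafb = 7 * wafb`.
#'
#' The default fixed effects are the multi-year coefficient set of the
#' published 'Braeburn' SSC accumulation model (intercept 3.78 % SSC, weekly
#' slope 0.31 % SSC, year/sector/crop-load/temperature/calcium main effects),
#' with per-week interaction slopes reconstructed from the published
#' time-dependent treatment-effect table, so that e.g. the top-sector offset
#' grows from ~0.53 % SSC at 40 DAFB to ~0.89 % SSC at 140 DAFB. Default
#' variance components (tree/fruit intercept sd 0.3, slope sd 0.02, residual
#' sd 0.3 % SSC) put the conditional RMSE near the ~0.48 % SSC scale of that
#' model. The default design (237 trees, 1274 marked fruit over three
#' seasons, 14 weekly scans each) mirrors the published trial dimensions.
#'
#' @param years A data frame with columns `year`, `n_trees`, `n_fruit`; fruit
#'   are spread round-robin over the trees of their year.
#' @param weeks Sampling schedule in WAFB.
#' @param effects Named list of fixed effects (% SSC): `intercept`, `week`
#'   (slope per WAFB), and named vectors `year`, `sector`, `crop_load`,
#'   `temperature_trt`, `calcium` of offsets for non-baseline levels.
#'   Baselines (year 2016, bottom sector, standard crop load, ambient
#'   temperature, with calcium) have effect 0.
#' @param interactions Same structure as `effects$year` etc., in % SSC per
#'   week: time-dependent slopes added to `week` for non-baseline levels.
#' @param sd_tree_intercept,sd_tree_slope,sd_fruit_intercept,sd_fruit_slope,sd_residual
#'   Standard deviations of the random effects and residual, in % SSC
#'   (slopes: % SSC per week).
#' @param dropout Per-week probability that a marked fruit is lost (and its
#'   later scans with it); 0 keeps the design balanced.
#' @param seed Integer seed.
#'
#' @return An `orchard_config` object.
#' @export
orchard_config <- function(
    years = data.frame(year = c(2016, 2017, 2018),
                       n_trees = c(33, 96, 108),
                       n_fruit = c(198, 603, 473)),
    weeks = 7:20,
    effects = list(
      intercept = 3.78, week = 0.31,
      year = c(`2017` = 1.47, `2018` = 1.85),
      sector = c(middle = 0.11, top = 0.39),
      crop_load = c(light = -0.07, heavy = -0.03),
      temperature_trt = c(cold = 0.15, warm = 0.21),
      calcium = c(without = 0.17)),
    interactions = list(
      year = c(`2017` = 0, `2018` = 0),
      sector = c(middle = 0.0154, top = 0.0252),
      crop_load = c(light = 0.0161, heavy = -0.0070),
      temperature_trt = c(cold = -0.0119, warm = -0.0091),
      calcium = c(without = 0)),
    sd_tree_intercept = 0.3, sd_tree_slope = 0.02,
    sd_fruit_intercept = 0.3, sd_fruit_slope = 0.02,
    sd_residual = 0.3,
    dropout = 0,
    seed = 1L) {
  stopifnot(all(c("year", "n_trees", "n_fruit") %in% names(years)),
            nrow(years) >= 1, all(years$n_trees >= 1), all(years$n_fruit >= 1))
  if (length(weeks) == 0) abort("`weeks` schedule must be non-empty.")
  sds <- c(sd_tree_intercept, sd_tree_slope, sd_fruit_intercept,
           sd_fruit_slope, sd_residual)
  if (any(sds < 0)) abort("random-effect standard deviations must be >= 0.")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  needed <- c("intercept", "week", "year", "sector", "crop_load",
              "temperature_trt", "calcium")
  if (!all(needed %in% names(effects))) {
    abort("`effects` must name intercept, week and every treatment factor.")
  }
  structure(
    list(years = years, weeks = weeks, effects = effects,
         interactions = interactions,
         sd_tree_intercept = sd_tree_intercept, sd_tree_slope = sd_tree_slope,
         sd_fruit_intercept = sd_fruit_intercept,
         sd_fruit_slope = sd_fruit_slope, sd_residual = sd_residual,
         dropout = dropout, seed = seed),
    class = "orchard_config")
}

orchard_levels <- list(
  sector = c("bottom", "middle", "top"),
  crop_load = c("standard", "light", "heavy"),
  temperature_trt = c("ambient", "cold", "warm"),
  calcium = c("with", "without"))

# effect of a factor level: 0 for baseline / unlisted levels
level_effect <- function(table, level) {
  if (is.null(table)) return(rep(0, length(level)))
  v <- unname(table[level])
  v[is.na(v)] <- 0
  v
}

#' Generate a synthetic longitudinal orchard SSC table
#'
#' Simulates the nested random-intercept/random-slope process of
#' [orchard_config()]: treatments (crop load, cell-division temperature,
#' calcium) are randomised over trees in balanced proportions, fruit are
#' nested in trees with their canopy sector cycling bottom/middle/top, random
#' effects are drawn once per tree and once per fruit, and a residual is
#' drawn per observation.
#'
#' @param config An [orchard_config()] object.
#' @return A tibble with one row per scan: `fruit_id`, `tree_id`, `year`
#'   (factor), `wafb`, `dafb`, the treatment factors (baseline level first),
#'   and `ssc` in % SSC.
#' @examples
#' cfg <- orchard_config(years = data.frame(year = 2016, n_trees = 5,
#'                                          n_fruit = 15), seed = 2)
#' orchard <- generate_orchard(cfg)
#' head(orchard)
#' @export
generate_orchard <- function(config) {
  stopifnot(inherits(config, "orchard_config"))
  maybe_seed(config$seed)
  eff <- config$effects
  int <- config$interactions

  balanced_draw <- function(levels, n) sample(rep_len(levels, n))

  fruit <- purrr::pmap_dfr(config$years, function(year, n_trees, n_fruit) {
    trees <- tibble::tibble(
      tree_id = sprintf("%d_T%03d", year, seq_len(n_trees)),
      crop_load = balanced_draw(orchard_levels$crop_load, n_trees),
      temperature_trt = balanced_draw(orchard_levels$temperature_trt, n_trees),
      calcium = balanced_draw(orchard_levels$calcium, n_trees),
      u_tree0 = rnorm(n_trees, 0, config$sd_tree_intercept),
      u_tree1 = rnorm(n_trees, 0, config$sd_tree_slope))
    idx <- rep_len(seq_len(n_trees), n_fruit)           # round-robin over trees
    within <- stats::ave(idx, idx, FUN = seq_along)     # index within tree
    fr <- trees[idx, ]
    fr$year <- year
    fr$fruit_id <- sprintf("%s_F%02d", fr$tree_id, within)
    fr$sector <- orchard_levels$sector[(within - 1L) %% 3L + 1L]
    fr$u_fruit0 <- rnorm(n_fruit, 0, config$sd_fruit_intercept)
    fr$u_fruit1 <- rnorm(n_fruit, 0, config$sd_fruit_slope)
    fr
  })

  year_lab <- as.character(fruit$year)
  fruit$b_intercept <- eff$intercept +
    level_effect(eff$year, year_lab) +
    level_effect(eff$sector, fruit$sector) +
    level_effect(eff$crop_load, fruit$crop_load) +
    level_effect(eff$temperature_trt, fruit$temperature_trt) +
    level_effect(eff$calcium, fruit$calcium) +
    fruit$u_tree0 + fruit$u_fruit0
  fruit$b_slope <- eff$week +
    level_effect(int$year, year_lab) +
    level_effect(int$sector, fruit$sector) +
    level_effect(int$crop_load, fruit$crop_load) +
    level_effect(int$temperature_trt, fruit$temperature_trt) +
    level_effect(int$calcium, fruit$calcium) +
    fruit$u_tree1 + fruit$u_fruit1

  n_weeks <- length(config$weeks)
  obs <- fruit[rep(seq_len(nrow(fruit)), each = n_weeks), ]
  obs$wafb <- rep(config$weeks, nrow(fruit))
  obs$ssc <- obs$b_intercept + obs$b_slope * obs$wafb +
    rnorm(nrow(obs), 0, config$sd_residual)

  if (config$dropout > 0) {
    # fruit lost in week w lose that and all later scans
    lost_at <- 1L + stats::rgeom(nrow(fruit), config$dropout)
    keep <- rep(lost_at, each = n_weeks) > rep(seq_len(n_weeks), nrow(fruit))
    obs <- obs[keep, ]
  }

  tibble::tibble(
    fruit_id = obs$fruit_id, tree_id = obs$tree_id,
    year = factor(obs$year, levels = sort(unique(config$years$year))),
    wafb = obs$wafb, dafb = 7L * obs$wafb,
    sector = factor(obs$sector, levels = orchard_levels$sector),
    crop_load = factor(obs$crop_load, levels = orchard_levels$crop_load),
    temperature_trt = factor(obs$temperature_trt,
                             levels = orchard_levels$temperature_trt),
    calcium = factor(obs$calcium, levels = orchard_levels$calcium),
    ssc = obs$ssc)
}

#' Generate synthetic harvest comparison samples
#'
#' Emulates the harvest-time method comparison: destructive refractometer
#' values from pooled fruit batches (the top halves of `batch_size` apples
#' blended together, so batch means carry `sd_fruit / sqrt(batch_size)`
#' of the fruit-to-fruit variation plus blender noise) versus non-destructive
#' single-fruit SSC predicted by a spectral calibration model, which carries
#' the full fruit variation plus model error. Both methods share the same
#' treatment-level means, i.e. the generator is unbiased between methods.
#'
#' @param n_levels Number of treatment levels (sector x treatment cells).
#' @param n_destructive,n_nondestructive Samples per level and method.
#' @param mean_ssc Grand mean at harvest, % SSC.
#' @param sd_level Between-level sd of true means, % SSC.
#' @param sd_fruit Fruit-to-fruit sd, % SSC.
#' @param batch_size Number of apples pooled per destructive batch.
#' @param blender_sd Additional sd of the pooled laboratory measurement.
#' @param model_error_sd Prediction error sd of the non-destructive model.
#' @param seed Integer seed.
#' @return A tibble with columns `method`, `treatment_level`, `ssc`.
#' @export
generate_harvest <- function(n_levels = 18, n_destructive = 4,
                             n_nondestructive = 7, mean_ssc = 11.7,
                             sd_level = 0.4, sd_fruit = 0.5, batch_size = 8,
                             blender_sd = 0.1, model_error_sd = 0.6,
                             seed = 1L) {
  stopifnot(n_levels >= 1, n_destructive >= 1, n_nondestructive >= 1)
  maybe_seed(seed)
  level_means <- mean_ssc + rnorm(n_levels, 0, sd_level)
  purrr::map_dfr(seq_len(n_levels), function(l) {
    dest <- level_means[l] +
      rnorm(n_destructive, 0, sd_fruit / sqrt(batch_size)) +
      rnorm(n_destructive, 0, blender_sd)
    nond <- level_means[l] + rnorm(n_nondestructive, 0, sd_fruit) +
      rnorm(n_nondestructive, 0, model_error_sd)
    tibble::tibble(
      method = rep(c("destructive", "nondestructive"),
                   c(n_destructive, n_nondestructive)),
      treatment_level = sprintf("L%02d", l),
      ssc = c(dest, nond))
  })
}
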
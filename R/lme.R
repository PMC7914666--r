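#' Fit a longitudinal SSC accumulation model
#'
#' Three nested specifications describe SSC trajectories over weeks after
#' full bloom (WAFB):
#'
#' * **Model 1** -- fixed intercept, WAFB slope, main effects for
#'   year/sector/crop load/cell-division temperature/calcium and their
#'   interactions with WAFB, plus independent random intercepts and slopes
#'   for trees and for fruit nested in trees.
#' * **Model 2** -- Model 1 without the time interactions (time-constant
#'   treatment effects), same random structure.
#' * **Model 3** -- Model 1's fixed effects with no random effects: a plain
#'   linear regression baseline.
#'
#' Mixed models are fitted with lme4; random intercepts and slopes are
#' uncorrelated within each grouping level (`(wafb || group)`), matching the
#' generative model of [orchard_config()]. REML (the default) supplies the
#' reported estimates and variance components; AIC and BIC always come from
#' the maximum-likelihood fit (an internal ML refit when `method = "REML"`)
#' so that models with different fixed effects are comparable. RMSE is the
#' root mean square of the conditional residuals. Boundary (zero-variance)
#' fits are flagged as singular, not rejected.
#'
#' Factors are coded against the baseline levels: year 2016 (first year
#' present), bottom sector, standard crop load, ambient temperature, with
#' calcium. Factors with a single observed level are dropped from the fixed
#' effects.
#'
#' @param data An orchard tibble (see [generate_orchard()]) with columns
#'   `ssc`, `wafb`, `fruit_id`, `tree_id` and the treatment factors.
#' @param model Model id: 1, 2 or 3.
#' @param method `"REML"` or `"ML"` (ignored for Model 3).
#' @return An `ssc_lme` object: the underlying fit, a coefficient table
#'   (estimate, standard deviation, t-value, the |t| > 2 significance flag),
#'   variance components, AIC/BIC/RMSE and design counts.
#' @seealso [model_compare()], [evaluate_effects()], [sensitivity_models()]
#' @examples
#' orchard <- generate_orchard(orchard_config(
#'   years = data.frame(year = 2016, n_trees = 12, n_fruit = 36),
#'   weeks = 7:14, seed = 3))
#' fit <- fit_ssc_lme(orchard, model = 2)
#' glance(fit)
#' @export
fit_ssc_lme <- function(data, model = 1, method = c("REML", "ML")) {
  method <- match.arg(method)
  if (!model %in% 1:3) abort("`model` must be 1, 2 or 3.")
  need <- c("ssc", "wafb", "fruit_id", "tree_id")
  if (!all(need %in% names(data))) {
    abort(paste("data must contain columns:", paste(need, collapse = ", ")))
  }
  tree_per_fruit <- tapply(data$tree_id, data$fruit_id,
                           function(x) length(unique(x)))
  if (any(tree_per_fruit > 1)) {
    abort("non-nested design: some fruit_id maps to more than one tree_id.")
  }

  factors <- intersect(c("year", "sector", "crop_load", "temperature_trt",
                         "calcium"), names(data))
  data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(factors), droplevels))
  factors <- factors[vapply(data[factors],
                            function(x) length(unique(x)) > 1, logical(1))]
  mains <- paste(c("wafb", factors), collapse = " + ")
  ints <- if (length(factors)) {
    paste(paste0("wafb:", factors), collapse = " + ")
  } else NULL
  fixed <- switch(as.character(model),
    "1" = paste(c(mains, ints), collapse = " + "),
    "2" = mains,
    "3" = paste(c(mains, ints), collapse = " + "))

  if (model == 3) {
    fml <- stats::as.formula(paste("ssc ~", fixed))
    fit <- lm(fml, data = data)
    cf <- summary(fit)$coefficients
    vc <- tibble::tibble(sd_tree_intercept = 0, sd_tree_slope = 0,
                         sd_fruit_intercept = 0, sd_fruit_slope = 0,
                         sd_residual = stats::sigma(fit))
    aic <- AIC(fit); bic <- BIC(fit); singular <- FALSE
  } else {
    fml <- stats::as.formula(paste(
      "ssc ~", fixed, "+ (wafb || tree_id) + (wafb || fruit_id)"))
    fit <- lme4::lmer(fml, data = data, REML = method == "REML",
                      control = lme4::lmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))
    cf <- summary(fit)$coefficients
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(grp, var) {
      r <- vcdf$sdcor[startsWith(vcdf$grp, grp) &
                      !is.na(vcdf$var1) & vcdf$var1 == var]
      if (length(r)) r[1] else 0
    }
    vc <- tibble::tibble(
      sd_tree_intercept = pick("tree_id", "(Intercept)"),
      sd_tree_slope = pick("tree_id", "wafb"),
      sd_fruit_intercept = pick("fruit_id", "(Intercept)"),
      sd_fruit_slope = pick("fruit_id", "wafb"),
      sd_residual = vcdf$sdcor[vcdf$grp == "Residual"])
    ml_fit <- if (method == "REML") lme4::refitML(fit) else fit
    aic <- AIC(ml_fit); bic <- BIC(ml_fit)
    singular <- lme4::isSingular(fit)
  }

  coefs <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    t_value = cf[, "t value"],
    significant = significance_flag(cf[, "t value"]))

  structure(
    list(fit = fit, model_id = model, method = method,
         coefficients = coefs, variance_components = vc,
         aic = aic, bic = bic,
         rmse = sqrt(mean(residuals(fit)^2)),
         n_obs = nrow(data),
         n_fruit = length(unique(data$fruit_id)),
         n_trees = length(unique(data$tree_id)),
         singular = singular,
         data_signature = c(nrow(data), sum(data$ssc), sum(data$ssc^2))),
    class = "ssc_lme")
}

#' @exportS3Method base::print
print.ssc_lme <- function(x, ...) {
  cat("<ssc_lme> Model", x$model_id, paste0("(", x$method, "),"),
      x$n_obs, "obs,", x$n_fruit, "fruit,", x$n_trees, "trees\n")
  cat(sprintf("AIC %.0f  BIC %.0f  RMSE %.3f %s\n", x$aic, x$bic, x$rmse,
              if (x$singular) "(singular fit)" else ""))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Coefficient table of a longitudinal SSC model
#'
#' @param x An `ssc_lme` fit.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (% SSC), `std_error`, `t_value`
#'   and the `significant` flag (|t| > 2).
#' @export
tidy.ssc_lme <- function(x, ...) x$coefficients

#' One-row summary of a longitudinal SSC model
#'
#' @param x An `ssc_lme` fit.
#' @param ... Unused.
#' @return A tibble with model id, estimation method, design counts,
#'   AIC/BIC (ML-based), conditional RMSE, the singularity flag and the
#'   random-effect standard deviations.
#' @export
glance.ssc_lme <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$model_id, method = x$method, n_obs = x$n_obs,
                   n_fruit = x$n_fruit, n_trees = x$n_trees,
                   aic = x$aic, bic = x$bic, rmse = x$rmse,
                   singular = x$singular),
    x$variance_components)
}

#' Statistical significance by the |t| > 2 rule
#'
#' Flags a coefficient as significant when the ratio of its estimate to its
#' standard deviation exceeds 2 in magnitude (strict inequality). This
#' deliberately side-steps degrees-of-freedom approximations for mixed
#' models.
#'
#' @param t_value Numeric vector of t-values (estimate / standard deviation).
#' @return Logical vector, `TRUE` iff `|t| > 2`.
#' @export
significance_flag <- function(t_value) {
  if (any(!is.finite(t_value))) abort("t-values must be finite.")
  abs(t_value) > 2
}

#' Compare nested SSC accumulation models
#'
#' @param ... `ssc_lme` fits on identical data (or a single list of them).
#' @return A tibble with one row per fit (AIC, BIC, RMSE and design counts)
#'   and a `best_aic` flag on the minimum-AIC row.
#' @export
model_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "ssc_lme")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "ssc_lme")))
  sig <- lapply(fits, `[[`, "data_signature")
  if (!all(vapply(sig, function(s) isTRUE(all.equal(s, sig[[1]])), logical(1)))) {
    abort("fits were made on differing data; comparison is not meaningful.")
  }
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$model_id, method = f$method,
                   aic = f$aic, bic = f$bic, rmse = f$rmse,
                   n_obs = f$n_obs, singular = f$singular)
  })
  dplyr::mutate(out, best_aic = .data$aic == min(.data$aic))
}

# coefficient lookup tolerant of interaction-name order
fit_coef <- function(coefs, name) {
  hit <- match(name, coefs$term)
  if (is.na(hit) && grepl(":", name)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    hit <- match(paste(rev(parts), collapse = ":"), coefs$term)
  }
  if (is.na(hit)) 0 else coefs$estimate[hit]
}

effect_columns <- list(
  sector = c(middle = "middle", top = "top"),
  crop_load = c(light = "light", heavy = "heavy"),
  temperature_trt = c(cold = "cold", warm = "warm"))

#' Time-dependent treatment effects
#'
#' Evaluates the fixed part of a trajectory model at a grid of days after
#' full bloom (DAFB): the base column is the expected SSC of the baseline
#' configuration (bottom sector, standard crop load, ambient temperature),
#' `intercept + slope * t`, and each offset column is the additive deviation
#' `main effect + interaction * t` for one non-baseline level. Offsets of
#' baseline levels are identically zero and every column is affine in DAFB.
#' Time is converted to the model's internal unit by `t = dafb / 7` weeks.
#'
#' @param fit An `ssc_lme` fit (Models 1--3) or an [effect_model()].
#' @param dafb DAFB grid at which to evaluate.
#' @param year Optional non-baseline year whose main effect and time
#'   interaction are folded into the base column (e.g. to tabulate effects
#'   for one season from a pooled fit); `NULL` keeps the baseline year.
#' @param digits Rounding of the reported % SSC values.
#' @return A tibble with columns `dafb`, `base`, `middle`, `top`, `light`,
#'   `heavy`, `cold`, `warm`.
#' @examples
#' anchors <- ssc_effect_anchors()
#' em <- effect_model_from_anchors(anchors)
#' evaluate_effects(em, dafb = seq(40, 140, 20))
#' @export
evaluate_effects <- function(fit, dafb = seq(40, 140, by = 20),
                             year = NULL, digits = 2) {
  coefs <- effect_coefficients(fit)
  wk <- dafb / 7
  base <- coefs$intercept + coefs$slope * wk
  if (!is.null(year)) {
    base <- base + coefs$lookup(paste0("year", year)) +
      coefs$lookup(paste0("wafb:year", year)) * wk
  }
  out <- tibble::tibble(dafb = dafb, base = base)
  for (fac in names(effect_columns)) {
    for (lv in names(effect_columns[[fac]])) {
      main <- coefs$lookup(paste0(fac, lv))
      inter <- coefs$lookup(paste0("wafb:", fac, lv))
      out[[effect_columns[[fac]][lv]]] <- main + inter * wk
    }
  }
  dplyr::mutate(out, dplyr::across(-"dafb", ~ round(.x, digits)))
}

# uniform coefficient accessor over fitted and constructed models
effect_coefficients <- function(fit) UseMethod("effect_coefficients")

#' @export
effect_coefficients.ssc_lme <- function(fit) {
  coefs <- fit$coefficients
  list(intercept = fit_coef(coefs, "(Intercept)"),
       slope = fit_coef(coefs, "wafb"),
       lookup = function(name) fit_coef(coefs, name))
}

#' @export
effect_coefficients.ssc_effect_model <- function(fit) {
  tables <- list(
    year = list(m = fit$effects$year, i = fit$interactions$year),
    sector = list(m = fit$effects$sector, i = fit$interactions$sector),
    crop_load = list(m = fit$effects$crop_load, i = fit$interactions$crop_load),
    temperature_trt = list(m = fit$effects$temperature_trt,
                           i = fit$interactions$temperature_trt),
    calcium = list(m = fit$effects$calcium, i = fit$interactions$calcium))
  lookup <- function(name) {
    inter <- startsWith(name, "wafb:")
    key <- sub("^wafb:", "", name)
    for (fac in names(tables)) {
      if (startsWith(key, fac)) {
        lv <- sub(paste0("^", fac), "", key)
        tab <- if (inter) tables[[fac]]$i else tables[[fac]]$m
        return(level_effect(tab, lv))
      }
    }
    0
  }
  list(intercept = fit$effects$intercept, slope = fit$effects$week,
       lookup = lookup)
}

#' Construct an effect model from explicit coefficients
#'
#' Builds an object that [evaluate_effects()] and [effect_range()] accept,
#' from plain fixed-effect values instead of a fitted model -- useful for
#' tabulating published coefficient sets or generator settings.
#'
#' @param intercept Baseline intercept at WAFB 0, % SSC.
#' @param week Slope per WAFB, % SSC.
#' @param effects,interactions Named lists of per-factor named vectors as in
#'   [orchard_config()].
#' @return An `ssc_effect_model` object.
#' @export
effect_model <- function(intercept, week, effects = list(),
                         interactions = list()) {
  structure(list(effects = c(list(intercept = intercept, week = week),
                             effects),
                 interactions = interactions),
            class = "ssc_effect_model")
}

#' Reconstruct an effect model from two tabulated anchor rows
#'
#' Every column of a time-dependent treatment-effect table is affine in
#' DAFB, so two tabulated rows determine the underlying coefficients: the
#' per-week slope of a column is `(v2 - v1) / (d2 - d1) * 7` and its
#' intercept at bloom is the value extrapolated to DAFB 0. Interior rows of
#' the table can then be reproduced by [evaluate_effects()].
#'
#' @param anchors A two-row tibble with columns `dafb`, `base`, `middle`,
#'   `top`, `light`, `heavy`, `cold`, `warm` (see [ssc_effect_anchors()]).
#' @return An `ssc_effect_model`.
#' @export
effect_model_from_anchors <- function(anchors) {
  stopifnot(nrow(anchors) == 2, "dafb" %in% names(anchors))
  d <- anchors$dafb
  if (d[1] == d[2]) abort("anchor rows must be at distinct DAFB.")
  line <- function(v) {
    slope_wk <- (v[2] - v[1]) / (d[2] - d[1]) * 7
    c(intercept = v[1] - slope_wk * d[1] / 7, slope = slope_wk)
  }
  b <- line(anchors$base)
  lv <- function(col) line(anchors[[col]])
  cols <- c("middle", "top", "light", "heavy", "cold", "warm")
  ls_ <- lapply(cols, lv)
  names(ls_) <- cols
  effect_model(
    intercept = unname(b["intercept"]), week = unname(b["slope"]),
    effects = list(
      sector = c(middle = unname(ls_$middle["intercept"]),
                 top = unname(ls_$top["intercept"])),
      crop_load = c(light = unname(ls_$light["intercept"]),
                    heavy = unname(ls_$heavy["intercept"])),
      temperature_trt = c(cold = unname(ls_$cold["intercept"]),
                          warm = unname(ls_$warm["intercept"]))),
    interactions = list(
      sector = c(middle = unname(ls_$middle["slope"]),
                 top = unname(ls_$top["slope"])),
      crop_load = c(light = unname(ls_$light["slope"]),
                    heavy = unname(ls_$heavy["slope"])),
      temperature_trt = c(cold = unname(ls_$cold["slope"]),
                          warm = unname(ls_$warm["slope"]))))
}

#' Published anchor rows of the 'Braeburn' time-dependent effect table
#'
#' The 40 and 140 DAFB rows of the published time-dependent treatment-effect
#' table for 'Braeburn' SSC accumulation (base trajectory plus
#' sector/crop-load/temperature offsets, % SSC). Together with
#' [effect_model_from_anchors()] these two rows determine the full table;
#' they drive the package's worked examples and reproduction script.
#'
#' @return A two-row tibble with columns `dafb`, `base`, `middle`, `top`,
#'   `light`, `heavy`, `cold`, `warm`.
#' @export
ssc_effect_anchors <- function() {
  tibble::tibble(
    dafb = c(40, 140),
    base = c(5.54, 9.96),
    middle = c(0.21, 0.43), top = c(0.53, 0.89),
    light = c(0.02, 0.25), heavy = c(-0.07, -0.17),
    cold = c(0.08, -0.09), warm = c(0.16, 0.03))
}

#' Range of a treatment factor's effect at one time point
#'
#' The spread (max minus min) of expected SSC across all levels of one
#' factor -- including the baseline level at offset zero -- at a given DAFB.
#'
#' @param table An effect table from [evaluate_effects()].
#' @param factor One of `"sector"`, `"crop_load"`, `"temperature_trt"`.
#' @param dafb A DAFB value present in `table`.
#' @return The range in % SSC.
#' @examples
#' em <- effect_model_from_anchors(ssc_effect_anchors())
#' effect_range(evaluate_effects(em, dafb = 140), "sector", 140)
#' @export
effect_range <- function(table, factor, dafb) {
  if (!factor %in% names(effect_columns)) {
    abort(paste0("unknown factor `", factor, "`."))
  }
  row <- table[table$dafb == dafb, , drop = FALSE]
  if (nrow(row) != 1) abort("`dafb` must match exactly one table row.")
  offsets <- c(0, as.numeric(row[, effect_columns[[factor]]]))
  max(offsets) - min(offsets)
}

#' Design-sensitivity refits of the full longitudinal model
#'
#' Refits Model 1 under three degraded designs: Model A keeps a random
#' subsample of trees with all their fruit; Model B keeps a random
#' subsample of fruit across all trees; Model C keeps the full data but adds
#' unbiased Gaussian noise to the SSC response. All refits use the full
#' model's specification, so the effect of the degraded design shows up in
#' the standard deviations and significance flags of the estimates.
#'
#' @param data An orchard tibble.
#' @param n_trees Trees retained in Model A.
#' @param n_fruit Fruit retained in Model B.
#' @param noise_sd Response noise sd for Model C, % SSC.
#' @param seed Integer seed for the subsampling and noise.
#' @return An `ssc_sensitivity` object: named list of `ssc_lme` fits
#'   (`multi_year`, `A`, `B`, `C`).
#' @export
sensitivity_models <- function(data, n_trees = 100, n_fruit = 500,
                               noise_sd = 1.0, seed = 1L) {
  trees <- unique(data$tree_id)
  fruit <- unique(data$fruit_id)
  if (length(trees) < n_trees) abort("not enough trees for Model A.")
  if (length(fruit) < n_fruit) abort("not enough fruit for Model B.")
  maybe_seed(seed)
  keep_trees <- sample(trees, n_trees)
  keep_fruit <- sample(fruit, n_fruit)
  data_c <- dplyr::mutate(data, ssc = add_lab_noise(.data$ssc, noise_sd))
  fits <- list(
    multi_year = fit_ssc_lme(data, model = 1),
    A = fit_ssc_lme(data[data$tree_id %in% keep_trees, ], model = 1),
    B = fit_ssc_lme(data[data$fruit_id %in% keep_fruit, ], model = 1),
    C = fit_ssc_lme(data_c, model = 1))
  structure(fits, class = "ssc_sensitivity")
}

#' Coefficient comparison across sensitivity refits
#'
#' @param x An `ssc_sensitivity` object.
#' @param ... Unused.
#' @return A long tibble of coefficient tables with a `model` column
#'   (`multi_year`, `A`, `B`, `C`).
#' @export
tidy.ssc_sensitivity <- function(x, ...) {
  purrr::map_dfr(names(x), function(nm) {
    dplyr::mutate(tidy(x[[nm]]), model = nm, .before = 1)
  })
}

#' @exportS3Method base::print
print.ssc_sensitivity <- function(x, ...) {
  cat("<ssc_sensitivity> refits:", paste(names(x), collapse = ", "), "\n")
  g <- purrr::map_dfr(names(x), function(nm) {
    dplyr::mutate(glance(x[[nm]]), label = nm, .before = 1)
  })
  print(g)
  invisible(x)
}
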
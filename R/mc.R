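#' Define one Monte Carlo sensitivity scenario
#'
#' A scenario fixes how calibration and validation sets are resampled from a
#' reference set of (derivative) spectra with laboratory SSC, and which
#' RMSEP breakdown is reported:
#'
#' * `sample_size` -- calibration size per year is varied; RMSEP overall and
#'   per validation year.
#' * `lab_error` -- Gaussian noise of sd `noise_sd` % SSC is added to the
#'   calibration responses only (validation references are never touched).
#' * `ssc_range` -- RMSEP within bins of the true validation SSC.
#' * `transfer` -- every training-year set in `train_years` is crossed with
#'   every validation year, mapping between-season model transfer.
#' * `temperature` -- RMSEP grouped by the scan temperature of the
#'   validation samples.
#'
#' @param mode One of `"sample_size"`, `"lab_error"`, `"ssc_range"`,
#'   `"transfer"`, `"temperature"`.
#' @param n_cal_per_year Calibration samples drawn per training year
#'   (typical grid: 20, 30, 40, 50, 75, 100, 125, 150, 175, 200, 300, 400,
#'   500).
#' @param noise_sd Laboratory-noise sd in % SSC (typical grid: 0, 0.1, 0.2,
#'   0.3, 0.4, 0.5, 0.75, 1.0, 2.0); used by `lab_error` mode.
#' @param train_years Years to calibrate on. A vector is one multi-year
#'   training set; a list of vectors (transfer mode) is one training set per
#'   element. `NULL` means all years in the reference set.
#' @param validate_years Years to validate on; `NULL` means all.
#' @param ssc_bins Breakpoints of the SSC bins for `ssc_range` mode.
#' @param n_validation_per_year Validation samples drawn per validation year.
#' @param reps Number of Monte Carlo repetitions.
#' @param max_components Candidate component cap passed to [fit_plsr()].
#' @param cv Component-selection scheme passed to [fit_plsr()].
#' @param seed Master seed; repetition `r` runs under `seed + r`, so any
#'   repetition can be reproduced in isolation.
#' @return An `mc_setting` object.
#' @seealso [run_mc_setting()]
#' @export
mc_setting <- function(mode = c("sample_size", "lab_error", "ssc_range",
                                "transfer", "temperature"),
                       n_cal_per_year = 500, noise_sd = 0,
                       train_years = NULL, validate_years = NULL,
                       ssc_bins = c(-Inf, 9, 10, 11, 12, 13, Inf),
                       n_validation_per_year = 100, reps = 500,
                       max_components = 7, cv = "loo", seed = 1L) {
  mode <- match.arg(mode)
  if (reps < 1) abort("`reps` must be at least 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (is.unsorted(ssc_bins)) abort("`ssc_bins` must be ordered.")
  if (n_cal_per_year < 2) abort("`n_cal_per_year` must be at least 2.")
  structure(
    list(mode = mode, n_cal_per_year = n_cal_per_year, noise_sd = noise_sd,
         train_years = train_years, validate_years = validate_years,
         ssc_bins = ssc_bins, n_validation_per_year = n_validation_per_year,
         reps = reps, max_components = max_components, cv = cv,
         seed = as.integer(seed)),
    class = "mc_setting")
}

#' Stratified calibration sampling
#'
#' Draws exactly `n_per_year` samples per year without replacement, so all
#' years contribute equal parts. Within each year the draw is balanced over
#' SSC quantile bins, which makes coverage of the SSC range explicit rather
#' than left to chance.
#'
#' @param data Reference tibble with `year` and the response column.
#' @param n_per_year Samples to draw per year.
#' @param years Years to draw from; `NULL` means all years present.
#' @param bins Number of within-year SSC quantile bins (1 disables the
#'   within-year balancing).
#' @param response Response column used for the binning.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return The sampled rows of `data`.
#' @export
stratified_sample <- function(data, n_per_year, years = NULL, bins = 4,
                              response = "ssc_ref", seed = NULL) {
  maybe_seed(seed)
  if (is.null(years)) years <- sort(unique(data$year))
  purrr::map_dfr(years, function(yr) {
    pool <- data[data$year == yr, , drop = FALSE]
    if (nrow(pool) < n_per_year) {
      abort(paste0("year ", yr, " has only ", nrow(pool),
                   " samples; ", n_per_year, " requested."))
    }
    if (bins <= 1 || n_per_year < bins) {
      return(pool[sample(nrow(pool), n_per_year), , drop = FALSE])
    }
    br <- unique(quantile(pool[[response]], probs = seq(0, 1, length.out = bins + 1)))
    bin <- cut(pool[[response]], breaks = br, include.lowest = TRUE)
    want <- floor(n_per_year / nlevels(bin))
    idx <- unlist(lapply(split(seq_len(nrow(pool)), bin), function(ix) {
      sample(ix, min(want, length(ix)))
    }), use.names = FALSE)
    short <- n_per_year - length(idx)
    if (short > 0) {
      rest <- setdiff(seq_len(nrow(pool)), idx)
      idx <- c(idx, sample(rest, short))
    }
    pool[idx, , drop = FALSE]
  })
}

#' Add unbiased laboratory noise to reference SSC values
#'
#' Emulates refractometer measurement error: independent draws from
#' `Normal(0, s^2)` are added to the responses. `s = 0` returns the input
#' unchanged (the noiseless standard calibration).
#'
#' @param y Reference % SSC vector.
#' @param s Noise standard deviation in % SSC.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return The perturbed vector.
#' @export
add_lab_noise <- function(y, s, seed = NULL) {
  if (s < 0) abort("noise sd `s` must be >= 0.")
  maybe_seed(seed)
  if (s == 0) return(y)
  y + rnorm(length(y), 0, s)
}

mc_rmsep_rows <- function(setting, model, validation, y_hat) {
  err2 <- (y_hat - validation$ssc_ref)^2
  overall <- tibble::tibble(group = "all", rmsep = sqrt(mean(err2)))
  by_group <- switch(setting$mode,
    ssc_range = {
      bin <- cut(validation$ssc_ref, breaks = setting$ssc_bins)
      tibble::tibble(group = as.character(levels(bin)),
                     rmsep = as.numeric(sqrt(tapply(err2, bin, mean))))
    },
    temperature = {
      g <- factor(validation$temperature_C)
      tibble::tibble(group = paste0("T", levels(g)),
                     rmsep = as.numeric(sqrt(tapply(err2, g, mean))))
    },
    {
      g <- factor(validation$year)
      tibble::tibble(group = as.character(levels(g)),
                     rmsep = as.numeric(sqrt(tapply(err2, g, mean))))
    })
  dplyr::bind_rows(overall, by_group)
}

#' Run one Monte Carlo scenario
#'
#' For each repetition: draw a validation set (simple random per validation
#' year), draw a calibration set disjoint from it (stratified per training
#' year, SSC-quantile balanced), perturb the calibration responses if in
#' `lab_error` mode, fit the PLSR calibration, and record RMSEP with the
#' scenario's breakdown. In `transfer` mode each training-year set is fitted
#' and evaluated against each validation year separately.
#'
#' @param setting An [mc_setting()].
#' @param reference Reference tibble of derivative spectra with `year`,
#'   `temperature_C` and `ssc_ref`.
#' @return A tidy tibble, one row per repetition x group (and x training set
#'   in transfer mode): `rep`, `train`, `group`, `rmsep`, plus the scenario
#'   descriptors `mode`, `n_cal_per_year`, `noise_sd`.
#' @seealso [mc_summarise()]
#' @export
run_mc_setting <- function(setting, reference) {
  stopifnot(inherits(setting, "mc_setting"))
  need <- c("year", "ssc_ref")
  if (!all(need %in% names(reference))) {
    abort("reference set must carry `year` and `ssc_ref`.")
  }
  all_years <- sort(unique(reference$year))
  val_years <- setting$validate_years %||% all_years
  train_sets <- setting$train_years %||% list(all_years)
  if (!is.list(train_sets)) train_sets <- list(train_sets)

  out <- purrr::map_dfr(seq_len(setting$reps), function(r) {
    set.seed(setting$seed + r)
    validation <- stratified_sample(reference, setting$n_validation_per_year,
                                    years = val_years, bins = 1)
    remaining <- dplyr::anti_join(reference, validation["sample_id"],
                                  by = "sample_id")
    purrr::map_dfr(train_sets, function(tr_years) {
      calibration <- stratified_sample(remaining, setting$n_cal_per_year,
                                       years = tr_years, bins = 4)
      if (setting$mode == "lab_error") {
        calibration$ssc_ref <- add_lab_noise(calibration$ssc_ref,
                                             setting$noise_sd)
      }
      model <- fit_plsr(calibration, max_components = setting$max_components,
                        cv = setting$cv)
      if (setting$mode == "transfer") {
        purrr::map_dfr(val_years, function(vy) {
          val_y <- validation[validation$year == vy, , drop = FALSE]
          y_hat <- predict(model, val_y)
          tibble::tibble(rep = r,
                         train = paste(tr_years, collapse = "-"),
                         group = as.character(vy),
                         rmsep = sqrt(mean((y_hat - val_y$ssc_ref)^2)))
        })
      } else {
        y_hat <- predict(model, validation)
        rows <- mc_rmsep_rows(setting, model, validation, y_hat)
        dplyr::mutate(rows, rep = r,
                      train = paste(tr_years, collapse = "-"),
                      .before = 1)
      }
    })
  })
  dplyr::mutate(out, mode = setting$mode,
                n_cal_per_year = setting$n_cal_per_year,
                noise_sd = setting$noise_sd)
}

#' Summarise Monte Carlo repetitions to mean and sd RMSEP
#'
#' @param results Output of [run_mc_setting()] (rows from several settings
#'   may be concatenated first).
#' @return A tibble with one row per scenario x training set x group:
#'   `mean_rmsep`, `sd_rmsep`, `reps`.
#' @export
mc_summarise <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$mode, .data$n_cal_per_year,
                    .data$noise_sd, .data$train, .data$group),
    mean_rmsep = mean(.data$rmsep),
    sd_rmsep = sd(.data$rmsep),
    reps = dplyr::n(),
    .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
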
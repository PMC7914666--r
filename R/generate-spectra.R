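#' Configuration for the synthetic Vis/NIR spectra generator
#'
#' Describes the forward model used to emulate point-spectrometer absorbance
#' scans of apple fruit: a smooth instrument baseline plus SSC-proportional
#' Gaussian absorption bands in the carbohydrate/water region, a small
#' temperature-induced band shift, and white measurement noise.
#'
#' The defaults emulate a handheld field spectrometer with 3 nm sampling over
#' a 310--1100 nm window, reference soluble solids content (SSC) spanning
#' 5--14 %, and reference scans taken at roughly 10, 20 and 30 degrees C.
#' The two default bands (840 and 960 nm, width 25 nm) overlap the
#' 729--975 nm modelling window so that a multivariate calibration is needed
#' to recover SSC, but remain identifiable: with zero noise the map from SSC
#' to the second-derivative spectrum is injective.
#'
#' @param n_samples Number of scans. A single count is split as evenly as
#'   possible across `years`; a vector of the same length as `years` gives
#'   per-year counts.
#' @param years Calendar years to tag scans with. Synthetic years are
#'   exchangeable: they share one forward model.
#' @param wavelength_start,wavelength_stop,wavelength_step Wavelength grid in
#'   nm; the grid is `seq(wavelength_start, wavelength_stop, wavelength_step)`.
#' @param ssc_range Lower/upper bound of the uniform reference SSC
#'   distribution, in % SSC.
#' @param noise_sd_absorbance Standard deviation of additive white noise, in
#'   absorbance units. The default 0.025 puts the validation RMSEP of a
#'   well-trained calibration near 0.6 % SSC, the error scale typical of
#'   orchard Vis/NIR SSC calibrations.
#' @param temperature_levels Fruit temperatures (degrees C) cycled across
#'   scans within each year.
#' @param temperature_shift_per_degC Band-center shift in nm per degree C away
#'   from 20 C, emulating temperature-dependent hydrogen bonding.
#' @param band_centers,band_widths,band_gains Gaussian band centers (nm),
#'   widths (nm) and gains (absorbance per % SSC).
#' @param seed Integer seed; regeneration with the same config is
#'   bit-identical.
#'
#' @return A `spectra_config` object (a validated list).
#' @seealso [generate_spectra()]
#' @export
spectra_config <- function(n_samples = 1500,
                           years = c(2016, 2017, 2018),
                           wavelength_start = 310,
                           wavelength_stop = 1100,
                           wavelength_step = 3,
                           ssc_range = c(5, 14),
                           noise_sd_absorbance = 0.025,
                           temperature_levels = c(10, 20, 30),
                           temperature_shift_per_degC = 0.2,
                           band_centers = c(840, 960),
                           band_widths = c(25, 25),
                           band_gains = c(0.020, 0.012),
                           seed = 1L) {
  if (any(n_samples <= 0)) abort("`n_samples` must be positive.")
  if (!length(n_samples) %in% c(1L, length(years))) {
    abort("`n_samples` must be a single count or one count per year.")
  }
  if (wavelength_step <= 0 || wavelength_stop <= wavelength_start) {
    abort("wavelength grid must be strictly increasing.")
  }
  if (length(ssc_range) != 2 || ssc_range[1] >= ssc_range[2]) {
    abort("`ssc_range` must be an increasing interval.")
  }
  if (noise_sd_absorbance < 0) abort("`noise_sd_absorbance` must be >= 0.")
  stopifnot(length(band_centers) == length(band_widths),
            length(band_centers) == length(band_gains),
            all(band_widths > 0))
  if (any(band_centers < wavelength_start | band_centers > wavelength_stop)) {
    abort("band centers must lie inside the wavelength grid.")
  }
  structure(
    list(n_samples = n_samples, years = years,
         wavelength_start = wavelength_start,
         wavelength_stop = wavelength_stop,
         wavelength_step = wavelength_step,
         ssc_range = ssc_range,
         noise_sd_absorbance = noise_sd_absorbance,
         temperature_levels = temperature_levels,
         temperature_shift_per_degC = temperature_shift_per_degC,
         band_centers = band_centers, band_widths = band_widths,
         band_gains = band_gains, seed = seed),
    class = "spectra_config")
}

# Smooth instrument/fruit baseline: broad pigment hump plus a gentle tilt.
spectra_baseline <- function(wl) {
  0.55 + 0.25 * exp(-((wl - 680) / 180)^2) + 1e-4 * (wl - 700)
}

# SSC-proportional band contribution at temperature_C, per unit % SSC.
spectra_band_response <- function(wl, config, temperature_C) {
  shift <- config$temperature_shift_per_degC * (temperature_C - 20)
  resp <- numeric(length(wl))
  for (b in seq_along(config$band_centers)) {
    mu <- config$band_centers[b] + shift
    resp <- resp + config$band_gains[b] *
      exp(-((wl - mu) / config$band_widths[b])^2 / 2)
  }
  resp
}

#' Generate synthetic absorbance spectra with known SSC
#'
#' Draws scans from the forward model described in [spectra_config()]:
#' `absorbance(lambda) = baseline(lambda) + ssc * sum_b gain_b *
#' gaussian(lambda; center_b + shift * (T - 20), width_b) + noise`.
#' Each scan carries its true (reference) SSC and scan temperature, so the
#' whole calibration pipeline is testable without field data.
#'
#' @param config A [spectra_config()] object.
#' @return A tibble with one row per scan: `sample_id`, `year`,
#'   `temperature_C`, `ssc_ref`, then one absorbance column per wavelength,
#'   named by its position in nm.
#' @examples
#' spectra <- generate_spectra(spectra_config(n_samples = 30, seed = 7))
#' dim(spectra)
#' @export
generate_spectra <- function(config) {
  stopifnot(inherits(config, "spectra_config"))
  maybe_seed(config$seed)
  wl <- seq(config$wavelength_start, config$wavelength_stop,
            by = config$wavelength_step)
  n_year <- if (length(config$n_samples) == 1L) {
    n <- config$n_samples
    k <- length(config$years)
    base <- n %/% k
    base + (seq_len(k) <= n %% k)
  } else {
    config$n_samples
  }
  meta <- purrr::map2_dfr(config$years, n_year, function(yr, n) {
    tibble::tibble(
      year = yr,
      temperature_C = rep_len(config$temperature_levels, n),
      ssc_ref = runif(n, config$ssc_range[1], config$ssc_range[2]))
  })
  meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
  base <- spectra_baseline(wl)
  # one band-response row per temperature level, recycled over scans
  resp <- vapply(meta$temperature_C,
                 function(tc) spectra_band_response(wl, config, tc),
                 numeric(length(wl)))
  A <- t(resp) * meta$ssc_ref + matrix(base, nrow(meta), length(wl), byrow = TRUE)
  if (config$noise_sd_absorbance > 0) {
    A <- A + matrix(rnorm(length(A), 0, config$noise_sd_absorbance),
                    nrow(meta), length(wl))
  }
  colnames(A) <- as.character(wl)
  dplyr::bind_cols(
    meta[, c("sample_id", "year", "temperature_C", "ssc_ref")],
    tibble::as_tibble(A))
}
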
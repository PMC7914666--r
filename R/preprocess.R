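#' @rdname spectra_matrix
#' @export
spectra_wavelengths <- function(data) {
  nm <- suppressWarnings(as.numeric(names(data)))
  nms <- names(data)[!is.na(nm)]
  as.numeric(nms)
}

#' Extract the spectral columns of a spectra table
#'
#' Spectra tables are wide tibbles: metadata columns plus one numeric column
#' per wavelength, named by its position in nm. `spectra_matrix()` returns
#' the wavelength columns as a numeric matrix (rows = scans),
#' `spectra_wavelengths()` the wavelengths themselves.
#'
#' @param data A spectra or derivative-spectra tibble.
#' @return A matrix with one column per wavelength, or a numeric vector of
#'   wavelengths in nm.
#' @export
spectra_matrix <- function(data) {
  wl <- spectra_wavelengths(data)
  if (length(wl) == 0) abort("no wavelength columns found.")
  m <- as.matrix(data[, as.character(wl), drop = FALSE])
  if (!all(is.finite(m))) abort("absorbance values must be finite.")
  m
}

spectra_meta <- function(data) {
  nm <- suppressWarnings(as.numeric(names(data)))
  data[, is.na(nm), drop = FALSE]
}

check_uniform_grid <- function(wl) {
  if (length(wl) < 2 || any(diff(wl) <= 0)) {
    abort("wavelength grid must be strictly increasing.")
  }
  steps <- diff(wl)
  if (diff(range(steps)) > 1e-8 * mean(steps)) {
    abort("wavelength grid must have a uniform step.")
  }
  steps[1]
}

#' Restrict spectra to a wavelength window
#'
#' Keeps wavelength columns with `low <= lambda <= high` (both bounds
#' inclusive; grid points are matched exactly, never interpolated). The
#' default window, 729--975 nm, is the SSC modelling window.
#'
#' @param data A spectra tibble (see [generate_spectra()]).
#' @param low,high Window bounds in nm.
#' @return The input tibble with out-of-window wavelength columns dropped.
#' @export
restrict_window <- function(data, low = 729, high = 975) {
  if (low >= high) abort("`low` must be below `high`.")
  wl <- spectra_wavelengths(data)
  keep <- wl[wl >= low & wl <= high]
  if (length(keep) == 0) abort("window retains no wavelengths.")
  dplyr::bind_cols(spectra_meta(data), data[, as.character(keep), drop = FALSE])
}

#' Savitzky-Golay second-derivative spectra on the modelling window
#'
#' Smooths each scan with a Savitzky-Golay polynomial filter and returns its
#' second derivative with respect to wavelength, cropped to the modelling
#' window. The filter is exact for polynomials up to `poly_order`, so a
#' quadratic spectrum yields a constant second derivative. Endpoint values
#' use the asymmetric filters of the same order; cropping from the full
#' 310--1100 nm grid to 729--975 nm keeps those ends well away from the
#' retained window.
#'
#' @param data A spectra tibble on a uniform wavelength grid.
#' @param window_points Filter length in grid points; odd and larger than
#'   `poly_order`. The default 9 points spans about 27 nm at 3 nm sampling.
#' @param poly_order Polynomial order of the local fit, at least 2.
#' @param low,high Retained window in nm (inclusive).
#' @return A tibble mirroring the input, with the wavelength columns replaced
#'   by second-derivative values (absorbance per nm^2) on the retained grid.
#' @examples
#' spectra <- generate_spectra(spectra_config(n_samples = 5))
#' d2 <- second_derivative(spectra)
#' range(spectra_wavelengths(d2))
#' @export
second_derivative <- function(data, window_points = 9, poly_order = 2,
                              low = 729, high = 975) {
  if (window_points %% 2 != 1) abort("`window_points` must be odd.")
  if (poly_order < 2) abort("`poly_order` must be at least 2.")
  if (window_points <= poly_order) {
    abort("`window_points` must exceed `poly_order`.")
  }
  wl <- spectra_wavelengths(data)
  step <- check_uniform_grid(wl)
  if (window_points > length(wl)) {
    abort("filter window is larger than the spectrum.")
  }
  X <- spectra_matrix(data)
  d2 <- t(apply(X, 1, signal::sgolayfilt,
                p = poly_order, n = window_points, m = 2, ts = step))
  if (nrow(X) == 1) d2 <- matrix(d2, nrow = 1)
  colnames(d2) <- as.character(wl)
  out <- dplyr::bind_cols(spectra_meta(data), tibble::as_tibble(d2))
  restrict_window(out, low, high)
}
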
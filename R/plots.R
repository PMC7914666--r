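#' Plot a handful of spectra
#'
#' @param data A spectra or derivative-spectra tibble.
#' @param n Number of scans to draw (taken from the top of the table).
#' @return A ggplot: absorbance (or derivative) against wavelength, coloured
#'   by reference SSC when present.
#' @export
plot_spectra <- function(data, n = 20) {
  data <- utils::head(data, n)
  wl <- spectra_wavelengths(data)
  long <- tidyr::pivot_longer(data, cols = dplyr::all_of(as.character(wl)),
                              names_to = "wavelength", values_to = "value")
  long$wavelength <- as.numeric(long$wavelength)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength, y = .data$value, group = .data$sample_id))
  p <- if ("ssc_ref" %in% names(long)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$ssc_ref), alpha = 0.7) +
      ggplot2::labs(colour = "SSC [%]")
  } else {
    p + ggplot2::geom_line(alpha = 0.7)
  }
  p + ggplot2::labs(x = "wavelength [nm]", y = "absorbance") +
    ggplot2::theme_minimal()
}

#' Cross-validation curve of a PLSR model
#'
#' @param object An `ssc_plsr` model fitted with cross-validation.
#' @param ... Unused.
#' @return A ggplot of CV RMSE against candidate component count, with the
#'   selected count marked.
#' @export
autoplot.ssc_plsr <- function(object, ...) {
  if (object$degenerate || all(is.na(object$cv_rmse_by_components))) {
    abort("no cross-validation curve available for this model.")
  }
  df <- tibble::tibble(components = seq_along(object$cv_rmse_by_components),
                       cv_rmse = object$cv_rmse_by_components)
  ggplot2::ggplot(df, ggplot2::aes(.data$components, .data$cv_rmse)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_components, linetype = 2) +
    ggplot2::labs(x = "latent components", y = "CV RMSE [% SSC]") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-laboratory calibration plot
#'
#' @param model An `ssc_plsr` model.
#' @param newdata Validation spectra carrying the reference column.
#' @param response Reference column name.
#' @return A ggplot of predicted against laboratory SSC with the identity
#'   and bias lines.
#' @export
plot_validation <- function(model, newdata, response = "ssc_ref") {
  df <- tibble::tibble(reference = newdata[[response]],
                       predicted = predict(model, newdata))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$reference)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "modelled SSC [%]", y = "laboratory SSC [%]") +
    ggplot2::theme_minimal()
}

#' RMSEP curves from a Monte Carlo summary
#'
#' @param object A summary tibble from [mc_summarise()] (rows of one mode).
#' @param x_var Which scenario descriptor to place on the x axis:
#'   `"n_cal_per_year"` or `"noise_sd"`.
#' @param ... Unused.
#' @return A ggplot of mean RMSEP with +/- one sd error bars per group.
#' @export
plot_mc_summary <- function(object, x_var = c("n_cal_per_year", "noise_sd"),
                            ...) {
  x_var <- match.arg(x_var)
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[x_var]], y = .data$mean_rmsep, colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rmsep - .data$sd_rmsep,
      ymax = .data$mean_rmsep + .data$sd_rmsep), width = 0) +
    ggplot2::labs(y = "RMSEP [% SSC]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Time-dependent treatment effect trajectories
#'
#' @param object An effect table from [evaluate_effects()].
#' @param ... Unused.
#' @return A ggplot of each offset column (and the base trajectory on its
#'   own facet) against DAFB.
#' @export
plot_effect_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = -"dafb",
                              names_to = "term", values_to = "ssc")
  long$panel <- ifelse(long$term == "base", "base [% SSC]",
                       "offset to base [% SSC]")
  ggplot2::ggplot(long, ggplot2::aes(.data$dafb, .data$ssc,
                                     colour = .data$term)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "days after full bloom", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
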
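#' Fit a PLSR calibration model for SSC
#'
#' Partial least squares regression (PLS1) by NIPALS: predictors and response
#' are centered, components are extracted by alternating weight/score/loading
#' updates with deflation of the predictor matrix only, and the y-loading is
#' recomputed against each component's scores. The number of components is
#' chosen by cross-validation as the candidate minimising the CV root mean
#' square error, with ties resolved toward fewer components; an optional
#' one-standard-error rule picks the smallest candidate whose CV mean squared
#' error is within one standard error of the minimum.
#'
#' @param data A tibble of (derivative) spectra with one numeric column per
#'   wavelength plus the response column; see [second_derivative()].
#' @param response Name of the response column, in % SSC.
#' @param max_components Largest candidate component count (capped at
#'   `n - 2` and the number of wavelengths).
#' @param cv Cross-validation scheme for component selection: leave-one-out
#'   (`"loo"`, the default), `"kfold"`, or `"none"` to use `max_components`
#'   directly.
#' @param k Number of folds for `cv = "kfold"`.
#' @param one_se Use the one-standard-error selection rule.
#' @param seed Optional seed for the k-fold assignment.
#' @return An object of class `ssc_plsr`: coefficients on the training
#'   wavelength grid, centering terms, selected component count,
#'   `cv_rmse_by_components`, and training metadata (`years`, `n`). A
#'   zero-variance response yields a degenerate model that predicts the
#'   constant response.
#' @seealso [predict.ssc_plsr()], [prediction_stats()]
#' @examples
#' d2 <- second_derivative(generate_spectra(spectra_config(n_samples = 60)))
#' fit <- fit_plsr(d2)
#' glance(fit)
#' @export
fit_plsr <- function(data, response = "ssc_ref", max_components = 7,
                     cv = c("loo", "kfold", "none"), k = 10,
                     one_se = FALSE, seed = NULL) {
  cv <- match.arg(cv)
  if (!response %in% names(data)) {
    abort(paste0("response column `", response, "` not found."))
  }
  X <- spectra_matrix(data)
  y <- data[[response]]
  if (anyNA(y) || anyNA(X)) abort("missing values are not supported.")
  n <- nrow(X)
  if (n < 3) abort("need at least 3 training samples.")
  wl <- spectra_wavelengths(data)
  years <- if ("year" %in% names(data)) sort(unique(data$year)) else NULL

  if (sd(y) == 0) {
    return(structure(
      list(degenerate = TRUE, y_mean = y[1], wavelengths = wl,
           n_components = 0L, cv_rmse_by_components = numeric(0),
           years = years, n = n),
      class = "ssc_plsr"))
  }

  ncomp <- min(max_components, n - 2L, ncol(X))
  folds <- switch(cv,
    loo = seq_len(n),
    kfold = {
      maybe_seed(seed)
      sample(rep_len(seq_len(min(k, n)), n))
    },
    none = NULL)

  if (is.null(folds)) {
    selected <- ncomp
    cv_rmse <- rep(NA_real_, ncomp)
  } else {
    sqerr <- plsr_cv_sqerr_cpp(X, y, ncomp, as.integer(folds))
    cv_rmse <- sqrt(colMeans(sqerr))
    selected <- which.min(cv_rmse)          # ties resolve to fewer components
    if (one_se) {
      mse <- colMeans(sqerr)
      se_min <- sd(sqerr[, selected]) / sqrt(n)
      selected <- which(mse <= mse[selected] + se_min)[1]
    }
  }

  fit <- nipals_fit_cpp(X, y, selected)
  used <- fit$n_used
  if (used == 0) {
    # predictors carry no usable variance: fall back to the mean model
    return(structure(
      list(degenerate = TRUE, y_mean = mean(y), wavelengths = wl,
           n_components = 0L, cv_rmse_by_components = cv_rmse,
           years = years, n = n),
      class = "ssc_plsr"))
  }
  beta <- fit$coefficients[, used]
  structure(
    list(degenerate = FALSE,
         coefficients = as.numeric(beta),
         intercept = fit$y_mean - sum(fit$x_mean * beta),
         x_mean = as.numeric(fit$x_mean), y_mean = fit$y_mean,
         weights = fit$weights, x_loadings = fit$x_loadings,
         y_loadings = as.numeric(fit$y_loadings), scores = fit$scores,
         wavelengths = wl, n_components = used,
         cv = cv, cv_rmse_by_components = cv_rmse,
         years = years, n = n),
    class = "ssc_plsr")
}

#' Predict SSC from a fitted PLSR model
#'
#' @param object An `ssc_plsr` model.
#' @param newdata A spectra tibble on the same wavelength grid as the
#'   training data, or a numeric matrix with one column per wavelength.
#' @param ... Unused.
#' @return A numeric vector of predicted % SSC.
#' @export
predict.ssc_plsr <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else spectra_matrix(newdata)
  if (!is.matrix(newdata)) {
    wl <- spectra_wavelengths(newdata)
    if (length(wl) != length(object$wavelengths) ||
        any(wl != object$wavelengths)) {
      abort("wavelength grid does not match the training grid.")
    }
  } else if (ncol(X) != length(object$wavelengths)) {
    abort("wavelength grid does not match the training grid.")
  }
  if (object$degenerate) return(rep(object$y_mean, nrow(X)))
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' Prediction diagnostics for a calibration model
#'
#' Root mean square error of prediction, adjusted prediction R-squared
#' (`1 - (1 - R2) (n - 1) / (n - n_predictors - 1)`, with the number of
#' latent components as `n_predictors`), and the bias line from an ordinary
#' least squares fit of the laboratory values on the predictions
#' (slope 1 / intercept 0 means no systematic error).
#'
#' @param y_hat Predicted % SSC.
#' @param y Laboratory reference % SSC.
#' @param n_predictors Number of predictors (latent components) used.
#' @return A one-row tibble: `rmsep`, `adjusted_r2`, `bias_slope`,
#'   `bias_intercept`, `n`.
#' @examples
#' prediction_stats(c(10.3, 9.6, 12, 11.5), c(10, 10, 12, 11), 2)
#' @export
prediction_stats <- function(y_hat, y, n_predictors = 1) {
  if (length(y_hat) != length(y)) abort("`y_hat` and `y` lengths differ.")
  n <- length(y)
  if (n < 3) abort("need at least 3 predictions.")
  rmsep <- sqrt(mean((y_hat - y)^2))
  r2 <- 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
  if (sd(y_hat) == 0) abort("zero variance in predictions: no bias line.")
  b <- coef(lm(y ~ y_hat))
  tibble::tibble(rmsep = rmsep, adjusted_r2 = adj,
                 bias_slope = unname(b[2]), bias_intercept = unname(b[1]),
                 n = n)
}

#' @exportS3Method base::print
print.ssc_plsr <- function(x, ...) {
  if (x$degenerate) {
    cat("<ssc_plsr> degenerate model: constant response", x$y_mean, "\n")
    return(invisible(x))
  }
  cat("<ssc_plsr> NIPALS PLSR,", x$n_components, "components,",
      x$n, "training samples\n")
  if (!all(is.na(x$cv_rmse_by_components))) {
    cat("CV RMSE by components:",
        paste(sprintf("%.3f", x$cv_rmse_by_components), collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy a PLSR model into per-wavelength coefficients
#'
#' @param x An `ssc_plsr` model.
#' @param ... Unused.
#' @return A tibble with `wavelength` (nm) and `coefficient`
#'   (% SSC per absorbance nm^-2 for derivative spectra).
#' @export
tidy.ssc_plsr <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(wavelength = x$wavelengths,
                          coefficient = 0))
  }
  tibble::tibble(wavelength = x$wavelengths, coefficient = x$coefficients)
}

#' One-row model summary of a PLSR fit
#'
#' @param x An `ssc_plsr` model.
#' @param ... Unused.
#' @return A tibble with the selected component count, its CV RMSE, training
#'   size and the degeneracy flag.
#' @export
glance.ssc_plsr <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    cv_rmse = if (x$n_components >= 1 &&
                  length(x$cv_rmse_by_components) >= x$n_components) {
      x$cv_rmse_by_components[x$n_components]
    } else NA_real_,
    n = x$n,
    degenerate = x$degenerate)
}

#' Serialize a PLSR model to a self-describing text artifact
#'
#' Writes (and reads back) the model as versioned JSON so calibrations can
#' be archived and reused across sessions. The serialized form keeps
#' everything needed for prediction (coefficients, centering terms,
#' wavelength grid) and the selection diagnostics; training scores and
#' loadings are not persisted.
#'
#' @param model An `ssc_plsr` model.
#' @param path File path.
#' @return `write_plsr()` returns `path` invisibly; `read_plsr()` returns the
#'   restored `ssc_plsr` model.
#' @export
write_plsr <- function(model, path) {
  stopifnot(inherits(model, "ssc_plsr"))
  keep <- setdiff(names(model), c("weights", "x_loadings", "scores"))
  payload <- c(list(format = "orchardssc-plsr", format_version = 1L),
               unclass(model)[keep])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_plsr
#' @export
read_plsr <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "orchardssc-plsr")) {
    abort("not an orchardssc PLSR model file.")
  }
  p$format <- NULL
  p$format_version <- NULL
  structure(p, class = "ssc_plsr")
}
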
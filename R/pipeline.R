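#' Run the full SSC analysis pipeline
#'
#' Chains the package's stages end to end, writing every intermediate table
#' as CSV so each stage communicates only through the declared file
#' contracts: generate spectra -> second-derivative preprocessing ->
#' PLSR calibration (with a held-out validation split) -> Monte Carlo
#' scenarios -> orchard generation and longitudinal models (comparison,
#' effect table, sensitivity refits when the data allow) -> harvest method
#' comparison. Stages without a configuration section are skipped; requested
#' stages with missing prerequisites fail validation before anything runs.
#'
#' All randomness derives from the configuration seeds, so rerunning the
#' same configuration reproduces every output byte for byte. Reported % SSC
#' values in output tables are rounded to 2 decimals; full precision is kept
#' internally between stages.
#'
#' @param config A `run_config` (see [read_run_config()] /
#'   [as_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return The run manifest (also written to `manifest.json`): per-stage
#'   output files with MD5 checksums and row counts, the seeds used and the
#'   package version.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$lme) && is.null(config$orchard)) {
    abort("lme stage requested but no `orchard` section configured.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  note <- function(name, path, rows) {
    files[[name]] <<- list(file = basename(path),
                           md5 = unname(tools::md5sum(path)), rows = rows)
  }
  round_ssc <- function(df, cols) {
    dplyr::mutate(df, dplyr::across(dplyr::any_of(cols), ~ round(.x, 2)))
  }
  path <- function(f) file.path(out_dir, f)

  derivative <- NULL
  if (!is.null(config$spectra)) {
    spectra <- generate_spectra(config$spectra)
    write_spectra_csv(round_ssc(spectra, "ssc_ref"), path("spectra.csv"))
    note("spectra", path("spectra.csv"), nrow(spectra))

    derivative <- second_derivative(spectra)
    write_spectra_csv(round_ssc(derivative, "ssc_ref"),
                      path("derivative.csv"))
    note("derivative", path("derivative.csv"), nrow(derivative))

    validation <- stratified_sample(
      derivative, max(2L, nrow(derivative) %/% (5L * length(unique(derivative$year)))),
      bins = 1, seed = config$seed + 10L)
    calibration <- dplyr::anti_join(derivative, validation["sample_id"],
                                    by = "sample_id")
    model <- fit_plsr(calibration)
    write_plsr(model, path("plsr_model.json"))
    note("plsr_model", path("plsr_model.json"), 1L)
    stats <- prediction_stats(predict(model, validation), validation$ssc_ref,
                              n_predictors = model$n_components)
    readr::write_csv(stats, path("plsr_stats.csv"))
    note("plsr_stats", path("plsr_stats.csv"), nrow(stats))
  }

  if (!is.null(config$mc)) {
    if (is.null(derivative)) {
      abort("mc stage requested but no `spectra` section configured.")
    }
    results <- purrr::map_dfr(config$mc, run_mc_setting,
                              reference = derivative)
    readr::write_csv(round_ssc(results, "rmsep"), path("mc_results.csv"))
    note("mc_results", path("mc_results.csv"), nrow(results))
    summary <- mc_summarise(results)
    readr::write_csv(round_ssc(summary, c("mean_rmsep", "sd_rmsep")),
                     path("mc_summary.csv"))
    note("mc_summary", path("mc_summary.csv"), nrow(summary))
  }

  if (!is.null(config$orchard)) {
    orchard <- generate_orchard(config$orchard)
    write_orchard_csv(round_ssc(orchard, "ssc"), path("orchard.csv"))
    note("orchard", path("orchard.csv"), nrow(orchard))

    if (!is.null(config$lme)) {
      fits <- lapply(config$lme$models, function(m) {
        fit_ssc_lme(orchard, model = m)
      })
      coefs <- purrr::map2_dfr(fits, config$lme$models, function(f, m) {
        dplyr::mutate(tidy(f), model = m, .before = 1)
      })
      readr::write_csv(coefs, path("lme_coefficients.csv"))
      note("lme_coefficients", path("lme_coefficients.csv"), nrow(coefs))
      if (length(fits) >= 2) {
        cmp <- model_compare(fits)
        readr::write_csv(cmp, path("lme_comparison.csv"))
        note("lme_comparison", path("lme_comparison.csv"), nrow(cmp))
      }
      eff <- evaluate_effects(fits[[1]])
      readr::write_csv(eff, path("lme_effects.csv"))
      note("lme_effects", path("lme_effects.csv"), nrow(eff))
    }
  }

  if (!is.null(config$harvest)) {
    harvest <- do.call(generate_harvest, config$harvest)
    cmp <- method_difference(harvest)
    readr::write_csv(round_ssc(harvest, "ssc"), path("harvest.csv"))
    note("harvest", path("harvest.csv"), nrow(harvest))
    readr::write_csv(glance(cmp), path("harvest_comparison.csv"))
    note("harvest_comparison", path("harvest_comparison.csv"), 1L)
  }

  manifest <- list(
    package = "orchardssc",
    version = as.character(utils::packageVersion("orchardssc")),
    seed = config$seed,
    stage_seeds = list(
      spectra = config$spectra$seed, orchard = config$orchard$seed,
      mc = lapply(config$mc, `[[`, "seed"),
      harvest = config$harvest$seed),
    outputs = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
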
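# CSV contracts: UTF-8, comma-separated, "." decimal, mandatory header.
# Unicode minus signs are normalised to ASCII hyphens on read.

normalise_minus <- function(df) {
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], function(x) gsub("−", "-", x, fixed = TRUE))
  df
}

#' Read and write spectra tables
#'
#' Spectra CSVs have one row per scan: `sample_id`, `year`, `temperature_C`,
#' `ssc_ref` (empty when unknown), then one column per wavelength named by
#' its position in nm. Derivative-spectra CSVs share the schema.
#'
#' @param data A spectra tibble.
#' @param path File path.
#' @return `read_spectra_csv()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_spectra_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- normalise_minus(df)
  wl <- suppressWarnings(as.numeric(names(df)))
  df[!is.na(wl)] <- lapply(df[!is.na(wl)], as.numeric)
  df
}

#' Read and write longitudinal orchard tables
#'
#' Orchard CSVs have one row per observation: `fruit_id`, `tree_id`, `year`,
#' `wafb`, `dafb`, `sector`, `crop_load`, `temperature_trt`, `calcium`,
#' `ssc`. On read, the treatment columns are restored as factors with the
#' baseline level first.
#'
#' @param data An orchard tibble.
#' @param path File path.
#' @return `read_orchard_csv()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_orchard_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_orchard_csv
#' @export
read_orchard_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- normalise_minus(df)
  df$year <- factor(df$year)
  for (fac in names(orchard_levels)) {
    if (fac %in% names(df)) {
      df[[fac]] <- factor(df[[fac]], levels = orchard_levels[[fac]])
    }
  }
  df
}

#' Read a pipeline run configuration
#'
#' Run configurations are YAML files with a global `seed`, a `spectra`
#' section ([spectra_config()] fields), an `orchard` section
#' ([orchard_config()] fields; `years` given as a table with `year`,
#' `n_trees`, `n_fruit`), an optional `mc` list of [mc_setting()] fields,
#' an optional `lme` section (`models:` ids), and an optional `harvest`
#' section ([generate_harvest()] fields). Omitted fields fall back to the
#' package defaults; omitted sections disable the corresponding stage.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object (nested list of validated configs).
#' @seealso [run_pipeline()]
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config A nested list with the same structure as the YAML file.
#' @export
as_run_config <- function(config) {
  seed <- config$seed %||% 1L
  out <- list(seed = as.integer(seed))
  if (!is.null(config$spectra)) {
    args <- config$spectra
    args$seed <- args$seed %||% seed
    out$spectra <- do.call(spectra_config, args)
  }
  if (!is.null(config$orchard)) {
    args <- config$orchard
    if (!is.null(args$years)) args$years <- as.data.frame(args$years)
    args$seed <- args$seed %||% (seed + 1L)
    out$orchard <- do.call(orchard_config, args)
  }
  if (!is.null(config$mc)) {
    out$mc <- lapply(seq_along(config$mc), function(i) {
      args <- config$mc[[i]]
      args$seed <- args$seed %||% (seed + 100L + i)
      do.call(mc_setting, args)
    })
  }
  if (!is.null(config$lme)) {
    models <- config$lme$models %||% 1:3
    if (!all(models %in% 1:3)) abort("`lme$models` must be from {1, 2, 3}.")
    out$lme <- list(models = models)
  }
  if (!is.null(config$harvest)) {
    args <- config$harvest
    args$seed <- args$seed %||% (seed + 2L)
    out$harvest <- args
  }
  structure(out, class = "run_config")
}
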
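Package: orchardssc
Title: Longitudinal Modelling of Apple Soluble Solids Content from Vis/NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-destructive monitoring of soluble solids content
    (SSC) in orchard fruit. Provides a synthetic generator for point-spectrometer
    Vis/NIR absorbance spectra with a known SSC forward model and for
    longitudinal orchard SSC records with nested tree/fruit random effects;
    Savitzky-Golay second-derivative preprocessing restricted to the
    729-975 nm modelling window; partial least squares regression (NIPALS)
    with leave-one-out cross-validated component selection; Monte Carlo
    sensitivity analysis of calibration sample size, laboratory reference
    error, SSC data range and between-season model transfer; linear
    mixed-effect models of SSC accumulation with time-dependent treatment
    effects and design-sensitivity refits; and a rank-based comparison of
    destructive versus non-destructive SSC determination at harvest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
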
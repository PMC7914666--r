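# orchardssc

Non-destructive monitoring of **soluble solids content** (SSC, in %,
≈ °Brix) in orchard fruit from handheld Vis/NIR spectra, and longitudinal
modelling of how SSC accumulates over a season under orchard treatments.

The package is aimed at horticultural researchers and chemometricians who
want to (a) calibrate SSC against destructive laboratory references, (b)
understand how many references that calibration really needs and how robust
it is, and (c) analyse repeated per-fruit SSC trajectories with the
appropriate nested mixed models. Because orchard campaigns rarely publish
raw spectra, the package ships a synthetic-data generator with a known
forward model, so the whole pipeline is testable and every claim in the
test suite is reproducible from code alone.

## What is inside

- **Synthetic data** — `generate_spectra()` draws absorbance scans
  `A(λ) = baseline(λ) + ssc · Σ gainᵦ · 𝒩(λ; centerᵦ + shift·(T−20), widthᵦ) + ε`
  on a 310–1100 nm grid; `generate_orchard()` simulates nested longitudinal
  SSC records `y = (β₀ + u_tree,0 + u_fruit,0) + (β₁ + u_tree,1 + u_fruit,1)·t + βX·X + βY·X·t + e`
  at the dimensions of a published three-season 'Braeburn' trial
  (237 trees, 1274 fruit).
- **Preprocessing** — `second_derivative()`: Savitzky–Golay second
  derivative (9 points, order 2) cropped to the 729–975 nm modelling
  window.
- **Calibration** — `fit_plsr()`: from-scratch NIPALS PLS1 with
  leave-one-out cross-validated component selection (≤ 7 components),
  `predict()`, `prediction_stats()` (RMSEP, adjusted prediction R², bias
  line), JSON model serialization.
- **Monte Carlo sensitivity** — `mc_setting()` / `run_mc_setting()`:
  repeated stratified resampling mapping RMSEP against calibration size,
  laboratory reference noise, SSC range bins, between-season transfer and
  scan temperature.
- **Longitudinal models** — `fit_ssc_lme()`: three nested trajectory models
  (full LME with time × treatment interactions; no interactions; no random
  effects) via lme4, compared by ML-based AIC/BIC (`model_compare()`);
  time-dependent treatment-effect tables (`evaluate_effects()`,
  `effect_range()`); design-sensitivity refits (`sensitivity_models()`);
  the |t| > 2 significance rule.
- **Harvest comparison** — `method_difference()` and `mann_whitney()` for
  destructive vs non-destructive agreement at harvest.
- **Orchestration** — `run_pipeline()` chains every stage through CSV
  contracts and writes a checksummed manifest; broom-style `tidy()` /
  `glance()` methods and `plot_*()` / `autoplot()` graphics throughout.

## Worked example

```r
library(orchardssc)
library(dplyr)

## calibrate SSC from synthetic spectra ------------------------------------
spectra <- generate_spectra(spectra_config(n_samples = 900, seed = 1))
d2      <- second_derivative(spectra)           # 729-975 nm, d2 absorbance
val     <- stratified_sample(d2, 60, bins = 1, seed = 2)
cal     <- anti_join(d2, val["sample_id"], by = "sample_id")

model <- fit_plsr(cal)
model
#> <ssc_plsr> NIPALS PLSR, 7 components, 720 training samples
#> CV RMSE by components: 1.402 0.946 0.823 0.739 0.704 0.683 0.668

prediction_stats(predict(model, val), val$ssc_ref, model$n_components)
#> # A tibble: 1 × 5
#>   rmsep adjusted_r2 bias_slope bias_intercept     n
#>   <dbl>       <dbl>      <dbl>          <dbl> <int>
#> 1 0.734       0.907      0.982          0.218   180
```

The CV curve levels off near 0.67 % SSC; held-out validation gives an RMSEP
of 0.73 % SSC with a bias line close to the identity (slope 0.98), i.e. a
usable, essentially unbiased calibration.

```r
## longitudinal treatment effects ------------------------------------------
orchard <- generate_orchard(orchard_config(seed = 1))   # 237 trees, 1274 fruit
fit <- fit_ssc_lme(orchard, model = 1)

tidy(fit) |>
  filter(term %in% c("(Intercept)", "wafb", "sectortop", "crop_loadheavy"))
#> # A tibble: 4 × 5
#>   term           estimate std_error t_value significant
#>   <chr>             <dbl>     <dbl>   <dbl> <lgl>
#> 1 (Intercept)      3.73     0.0819   45.5   TRUE
#> 2 wafb             0.312    0.00542  57.5   TRUE
#> 3 sectortop        0.435    0.0281   15.5   TRUE
#> 4 crop_loadheavy  -0.0344   0.0567   -0.607 FALSE

evaluate_effects(fit, dafb = seq(40, 140, 20))
#> # A tibble: 6 × 8
#>    dafb  base middle   top light heavy  cold  warm
#>   <dbl> <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1    40  5.51   0.24  0.58  0    -0.06  0.21  0.17
#> 2    60  6.4    0.28  0.65  0.05 -0.08  0.18  0.14
#> 3    80  7.29   0.32  0.72  0.09 -0.09  0.15  0.11
#> 4   100  8.18   0.36  0.79  0.14 -0.1   0.12  0.08
#> 5   120  9.07   0.4   0.86  0.18 -0.12  0.09  0.05
#> 6   140  9.96   0.44  0.93  0.23 -0.13  0.06  0.01
```

The fitted trajectory model recovers the generating coefficients: SSC rises
by 0.31 % per week from an early-season base near 5.5 %, fruit from the top
canopy sector run ~0.4 % SSC sweeter with the gap widening over the season
(0.58 → 0.93 % SSC between 40 and 140 days after full bloom), crop-load and
temperature effects are small, and the effect table is affine in time by
construction.

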
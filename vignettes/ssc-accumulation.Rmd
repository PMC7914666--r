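---
title: "Modelling soluble solids content accumulation from Vis/NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soluble solids content accumulation from Vis/NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardssc)
```

## The problem

Soluble solids content (SSC, in %, roughly °Brix) is the standard
refractometric proxy for sugar concentration in fruit. Measuring it
destructively is slow and consumes the fruit, so the development of SSC in
individual apples over a season cannot be followed that way. Handheld Vis/NIR
point spectrometers offer a way out: absorbance spectra of the intact fruit,
calibrated against a modest number of destructive laboratory references by
partial least squares regression (PLSR), turn every field scan into an SSC
estimate. Repeated scans of the same marked fruit then form longitudinal
trajectories that linear mixed-effect (LME) models can relate to orchard
treatments.

orchardssc implements that entire chain as composable, pipe-friendly
functions, together with a synthetic-data generator that makes every stage
testable without access to field data. The package answers four method
questions:

1. how many laboratory calibration samples a robust SSC calibration needs;
2. how sensitive the calibration is to laboratory (refractometer) error,
   to the covered SSC range, and to transferring a model between seasons;
3. how reduced experimental designs (fewer trees, fewer fruit, noisier
   response) degrade the precision of treatment-effect estimates;
4. whether non-destructive SSC at harvest agrees with destructive
   laboratory determination.

## The synthetic spectra generator

No spectral physics is implied beyond what a calibration exercise needs. A
scan on the wavelength grid $\lambda$ (default 310–1100 nm in 3 nm steps) is

$$A(\lambda) = b(\lambda) + \mathrm{ssc}\sum_k g_k\,
  \exp\!\left(-\tfrac{(\lambda - c_k - \delta (T - 20))^2}{2 w_k^2}\right)
  + \varepsilon(\lambda),$$

with a smooth instrument/pigment baseline $b$, two Gaussian absorption bands
(centers $c_k$ = 840 and 960 nm, widths $w_k$ = 25 nm) whose amplitude is
proportional to SSC with gains $g_k$ = 0.020 and 0.012 AU per % SSC, a
temperature shift $\delta$ = 0.2 nm/°C around 20 °C emulating
temperature-dependent hydrogen bonding, and white noise
$\varepsilon \sim N(0, \sigma_A^2)$. The bands sit inside the 729–975 nm
modelling window, where real carbohydrate and water features lie, and they
overlap, so recovery of SSC genuinely requires a multivariate calibration;
with $\sigma_A = 0$ the map from SSC to the second-derivative spectrum is
injective (tested). Reference SSC is uniform on 5–14 % and scans cycle
through ~10/20/30 °C, emulating a laboratory reference protocol.

The noise default $\sigma_A = 0.025$ AU was fixed once so that a well-trained
multi-year calibration (500 samples/year) reaches a validation RMSEP near
0.6 % SSC — the error scale typical of orchard Vis/NIR SSC calibrations —
and was not revisited afterwards. What the generator deliberately omits:
light scattering, skin/flesh heterogeneity, daylight background (assumed
corrected in-device), and between-season distribution shifts (synthetic
years are exchangeable). Consequently, passing sensitivity checks here shows
the *machinery* behaves correctly under the stated conditions; absolute
field RMSEP values are not claimed.

## Preprocessing

`second_derivative()` applies a Savitzky–Golay smoothing derivative
(default: 9-point window ≈ 27 nm, polynomial order 2, second derivative)
and crops to the inclusive 729–975 nm window, matching grid points exactly
(no interpolation). The choice of a Savitzky–Golay filter is a design
decision — the derivative method is otherwise unconstrained — and both
window length and polynomial order are exposed. The filter is polynomial-
exact: quadratics give their exact curvature, lines give zero, and the
operator is linear (all tested against a finite-difference oracle).

## PLSR calibration

`fit_plsr()` is a from-scratch PLS1 NIPALS implementation (compiled core):
predictors and response are centered; each component takes the weight vector
$w \propto X^\top y$, scores $t = Xw$, x-loading $p = X^\top t / t^\top t$
and y-loading $q = y^\top t / t^\top t$; only $X$ is deflated. Regression
coefficients for $k$ components are $W_k (P_k^\top W_k)^{-1} q_k$. The
component count (at most 7) is selected by leave-one-out cross-validation at
the global RMSE minimum, ties toward fewer components; a one-standard-error
rule is available behind a flag, as is k-fold CV for very large calibration
sets. With the full component count PLSR reproduces ordinary least squares,
which is the oracle used in the tests (agreement to 1e−8); a zero-variance
response yields a degenerate mean model rather than an error.

`prediction_stats()` reports RMSEP, adjusted prediction R² (with the number
of latent components as the predictor count), and a bias line from
regressing laboratory values on predictions.

## Monte Carlo sensitivity framework

`mc_setting()` + `run_mc_setting()` implement repeated stratified
resampling: per repetition a validation set is drawn (simple random per
year), then a calibration set disjoint from it, stratified by year with
within-year SSC-quartile balancing (on by default; the stratification beyond
"equal parts per year" is a design decision that makes range coverage
explicit). Five modes vary calibration size per year
(20…500), add unbiased Gaussian noise to *calibration* responses only
(s = 0…2 % SSC), split RMSEP by SSC bins (<9 to >13 %), cross training-year
sets with validation years (transfer matrices), or group RMSEP by scan
temperature. Published descriptions of this kind of simulation use either
100 or 500 repetitions in different places; `reps` is a parameter (default
500) and the discrepancy is noted here rather than resolved. Per-repetition
seeds derive from the master seed by a counter (`seed + rep`), so any single
repetition is reproducible in isolation.

Validation-set sizes differ between published scenario descriptions (100,
200 or 300 per year); each `mc_setting` therefore carries its own
`n_validation_per_year` (default 100).

## Longitudinal mixed models

For observation $k$ of fruit $i$ on tree $j$:

$$y_{ijk} = \beta_0 + u_{j,0} + u_{i,0} + (\beta_1 + u_{j,1} + u_{i,1})\,t_k
  + \beta_X X_i + \beta_Y X_i t_k + e_{ijk},$$

with time $t_k$ in weeks after full bloom (WAFB; days after full bloom
convert as dafb = 7·wafb), treatment/main-effect covariates $X_i$ (year,
canopy sector, crop load, cell-division temperature, calcium), and
independent Gaussian random intercepts and slopes for trees and for fruit
nested in trees — intercept–slope correlations are deliberately excluded
because the generative model specifies separate univariate Normals.
Model 2 drops the interactions ($\beta_Y = 0$); Model 3 drops all random
effects (plain regression baseline). Fitting goes through lme4 with
`(wafb || tree_id) + (wafb || fruit_id)`; REML supplies reported estimates
and variance components, while AIC/BIC always come from an ML refit so
nested fixed-effect structures are comparable. Significance uses the
|t| > 2 rule; degrees-of-freedom approximations (Satterthwaite and friends)
are intentionally out of scope. Boundary (zero-variance) fits are flagged
`singular`, not rejected.

`evaluate_effects()` tabulates the fixed part $\beta_0 + \beta_1 t$ (base)
and per-level offsets $\beta_X + \beta_Y t$ on a DAFB grid; every column is
affine in DAFB by construction, values are reported to 0.01 % SSC.
A pooled multi-year fit can be specialised to one season via the `year`
argument, which folds that year's main effect and time interaction into the
base column; tabulating from a season-specific refit is the documented
alternative route. `effect_range()` returns the max–min spread of a factor
at one DAFB including the baseline level at offset zero.
`effect_model_from_anchors()` inverts the tabulation: two rows of such a
table determine intercept and per-week slope of every column, which is how
the package reconstructs a full coefficient set from the two published
anchor rows bundled as `ssc_effect_anchors()`.

`sensitivity_models()` refits Model 1 under three degraded designs (100
trees; 500 fruit; +1.0 % SSC response noise) and reports the inflated
standard deviations.

### Generator defaults for the orchard

The default fixed effects are the published multi-year coefficient set
(intercept 3.78, weekly slope 0.31, year offsets 1.47/1.85, sector
0.11/0.39, crop load −0.07/−0.03, temperature 0.15/0.21, calcium 0.17
% SSC). The interaction slopes are reconstructed from the published
time-dependent effect table via the anchor inversion above (e.g. top sector
0.0252 % SSC per week); the two published sources are mutually consistent
under exactly this affine structure, which is a strong check of the
reconstruction. Interactions of year and calcium with time are not
published and default to zero. Variance components are not published;
the defaults σ(tree, intercept) = σ(fruit, intercept) = 0.3,
σ(tree, slope) = σ(fruit, slope) = 0.02 and σ(e) = 0.3 % SSC were chosen
once to match the published residual error scale of the full model.
The default design — 237 trees and 1274 fruit over three seasons
(33/198, 96/603, 108/473 trees/fruit per year), fruit spread round-robin
over trees with sectors cycling bottom/middle/top, treatments randomised
at tree level in balanced proportions, 14 weekly scans at WAFB 7–20 —
mirrors the published trial dimensions. Tree counts per year are not all
published; the 2018 count is set so the total matches the published 237.
An optional per-week dropout probability (default 0) emulates fruit loss
and exercises unbalanced-data handling.

## Harvest method comparison

`method_difference()` compares destructive and non-destructive SSC at
harvest: per-method means/sds, per-treatment-level differences (absolute
*and* signed — the absolute reading matches the published summary
convention, the signed one shows the absence of bias), and a two-sided
Mann–Whitney–Wilcoxon test (exact for small untied samples, midranks with
continuity-corrected normal approximation otherwise). The harvest generator
pools eight fruit per destructive batch (blender emulation), so destructive
values are less variable than single-fruit model predictions, as observed
in practice.

## Numerical choices and degenerate inputs

- Ties in CV component selection resolve to fewer components.
- A calibration response with zero variance returns a degenerate mean
  model; predictors with no usable variance likewise fall back to the mean.
- `restrict_window()` errors on an empty window; the derivative filter
  errors on non-uniform grids and on windows longer than the spectrum.
- Mixed-model fits use the bobyqa optimizer; singular fits are flagged.
- Stratified sampling errors explicitly, naming the year, when a year's
  pool is too small.
- CSV output rounds % SSC to 2 decimals; all internal computation is full
  precision. Unicode minus signs are normalised to ASCII on read.

## Problem sizes used by the test suite

The suite exercises the full published dimensions where the claim depends
on them (coefficient recovery: 20 replicates of 237 trees / 1274 fruit /
17,836 observations) and reduced but structurally identical designs
elsewhere (model-ordering checks: two years × 25 trees × 90 fruit;
Monte Carlo properties: 700 reference samples per year, 50 repetitions per
scenario). These sizes are the package's own trade-off between sampling
error and turnaround; all thresholds were fixed before the runs they gate.

## Known limitations

- The spectral forward model is phenomenological; no scattering, no
  radiative transfer, no cultivar differences.
- Synthetic years are exchangeable, so between-season transfer degradation
  (which dominates real transfer matrices) is *not* reproduced — only the
  symmetry of the procedure is testable.
- Equatorial/sun-side duplicate scans are not modelled; one scan per fruit
  and occasion.
- Dry-matter content and fruit growth modelling are out of scope.
```{r session}
sessionInfo()
```
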
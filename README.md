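# maradsm

Abundance and spatial structure of the mara (*Dolichotis patagonum*) —
and other low-density, wide-ranging terrestrial species — from
line-transect distance-sampling surveys, via density surface models
(DSMs).

Field surveys of this kind record, along ~1,000 km of transect lines,
the perpendicular distance and size of every detected animal group.
Two problems stand between those records and a density map: detection
is imperfect and decays with distance from the line, and density varies
across the landscape with habitat and human presence. `maradsm`
implements the full inference chain:

1. **Detection function.** Half-normal, hazard-rate and uniform keys
   fitted to truncated perpendicular distances by conditional maximum
   likelihood; model choice by a quantified *shape criterion* (spiked
   fits near zero distance are discarded) then AIC; average
   detectability `p = (1/w)∫₀ʷ g(y) dy` with full parameter covariance.
2. **Segment counts.** Transects split into 1.8 km segments; individual
   counts, strip areas `A_j = 2 w l_j`, and habitat covariates attached;
   covariates screened for collinearity (Pearson |r| < 0.7, priority to
   ecologically meaningful variables).
3. **Density surface model.** The offsetted count GAM

   `E(n_j) = p̂ · A_j · exp[ β₀ + Σₖ fₖ(z_jk) ]`

   with shrinkage penalized splines (REML smoothness selection,
   effective df allowed below 1), backward term selection at α = 0.01,
   and Tweedie / negative-binomial / quasi-Poisson responses compared on
   randomized-quantile residuals.
4. **Prediction and uncertainty.** Abundance on a masked grid of 4 km²
   cells; detection-function uncertainty propagated into per-cell and
   overall variance by a derivative-column refit (with an independence
   delta-method fallback); residual correlograms along transects.
5. **Synthetic surveys.** A first-class generator (landscape rasters,
   inhomogeneous-Poisson populations, systematic transects,
   detection-thinned sightings) calibrated to realistic survey
   conditions — ~0.11 sightings/km, group sizes 2.65 ± 1.76, ~107
   retained sightings — so every stage is testable by parameter
   recovery.

## Worked example

Simulate a survey under the default calibrated conditions and run the
whole pipeline:

```r
library(maradsm)

cfg <- validate_config(list(seed = 1))
dat <- simulate_dataset(cfg)   # landscape, population, transects, sightings
res <- run_pipeline(cfg, data = dat)
print(res)
```

which prints (numbers from this exact seed):

```
# Density surface model report

Detection: half_normal key, 106 sightings retained, w = 287.6 m, p_hat = 0.799

Family comparison (terms | Exp.Dev. | Ab. | SE | CV):
  tweedie       s(ranch_dist) s(longitude) | 16.4% | 2429 | 392 | 0.16
  negbin        s(ranch_dist) s(longitude) | 14.3% | 2315 | 488 | 0.21
  quasipoisson  s(ranch_dist) s(longitude) | 21.3% | 2910 | 599 | 0.21

Selected model: negbin
  s(ranch_dist): edf = 1.98, p = 0.00231
  s(longitude): edf = 1.39, p = 1.14e-05
  explained deviance = 14.3%

Abundance: 2315 individuals over 3600 km^2 (0.64 / km^2)
Uncertainty: SE = 488, CV = 0.21 (refit propagation)
Residual correlogram: max |r| = 0.10 over 10 lags
```

Reading this: of 118 simulated sightings, the 10% most distant were
dropped, fixing the truncation distance at 288 m; the half-normal key
passed the shape criterion with average detectability 0.80. All three
response families retained the same two smooths — distance to the
nearest ranch building and longitude, the two covariates the generator
actually uses — and the selected model estimates 2,315 individuals over
the 3,600 km² prediction area (true simulated total for this seed:
2,330), with a CV of 0.21 that includes the detection-function
uncertainty. Adjacent-segment residual correlation stays below 0.2.

Per-stage functions (`truncate_distances()`, `fit_key_function()`,
`segment_transects()`, `fit_dsm()`, `select_terms()`,
`predict_abundance()`, `propagate_variance()`,
`residual_correlogram()`, ...) expose every intermediate step; a thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`. Real
per-segment tables (e.g. published supplementary data) enter through
`read_segment_table()`.

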
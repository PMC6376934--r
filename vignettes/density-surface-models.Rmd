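---
title: "Density surface models for mara line-transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density surface models for mara line-transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The mara (*Dolichotis patagonum*) is a large caviomorph rodent of the
Patagonian drylands that occurs at low density over large, sheep-ranched
landscapes. Estimating its abundance and mapping where it is abundant
requires correcting raw counts for imperfect detection and relating
density to habitat covariates. This package implements the standard
two-stage approach for such surveys:

1. **Line-transect distance sampling.** Perpendicular distances of
   detected groups are used to fit a detection function `g(y)` (the
   probability of detecting a group at distance `y` from the line, with
   `g(0) = 1`), yielding an average detectability
   `p = integral of g over [0, w] / w` within the truncation distance
   `w`.
2. **A density surface model (DSM).** Transects are cut into short
   segments; the individual count in segment `j` is modeled as

   `E(n_j) = p * A_j * exp(b0 + sum_k f_k(z_jk))`

   where `A_j = 2 w l_j` is the two-sided segment strip area, `z_jk`
   are habitat covariates at the segment, and `f_k` are penalized
   regression splines. The fitted surface is evaluated over a grid of
   4 km^2 cells to give a density map, a total abundance, and a
   variance that includes the detection-function uncertainty.

Every stage is also backed by a synthetic survey generator, so the whole
chain can be verified by parameter recovery on data whose truth is known.

# Detection function

Candidate keys are the half-normal `exp(-y^2 / (2 sigma^2))`, the
hazard-rate `1 - exp(-(y/sigma)^(-b))` and the uniform `g = 1`. Each is
fitted to the retained distances by maximizing the conditional likelihood
`prod g(y_i) / mu`, `mu = integral of g over [0, w]`. The half-normal
`mu` has a closed form via the normal CDF (tested against adaptive
quadrature at 1e-8); the hazard-rate integral uses adaptive quadrature.
Parameters are optimized on the log scale — a bracketed golden-section
search for the one-parameter half-normal (robust to the likelihood
plateau as `sigma` grows), Nelder-Mead with restarts for the hazard-rate
— and the covariance is the inverse observed information mapped back to
the natural scale.

**Truncation.** Following standard practice the most extreme 10% of
distances are discarded before fitting: the `ceiling(0.1 n)` largest
values are removed (ties with the cutoff go too), and `w` is the largest
retained distance. The ceiling rule reproduces the canonical worked
example of 119 sightings reducing to 107.

**Shape criterion.** Detection functions should have a "shoulder" —
near-certain detection close to the line — and fits spiked at zero are
not credible. The package quantifies this visual criterion with a spike
index `g(w/20) / g(0)`; a candidate with an index below 0.8 (the
configurable default) is discarded, and the survivor with the lowest AIC
is selected. Ties prefer fewer parameters, then a fixed key order. The
half-normal can only be flagged when `sigma` is small against `w`
(its index is bounded below by `exp(-w^2 / (800 sigma^2))`), which is
exactly the regime in which it is genuinely spiked.

# Segments, counts and covariates

Each transect of length `L` is split into `m = max(1, round(L / 1.8 km))`
equal segments, preserving all effort without remainder scraps; 1,085.4
km at the 1.8 km nominal length gives exactly 603 segments. Along-track
intervals are half-open `[start, end)` (last closed) so a sighting
projected exactly onto a boundary goes to the downstream segment,
deterministically. Counts are individuals (group sizes summed), matching
the constant-`p` count method: with no covariates in the detection
function, detectability is the same in every segment and enters only
through the offset.

Covariates are sampled at the segment midpoint cell of the landscape
rasters; the distance to the nearest ranch building is recomputed exactly
from the building coordinates where available. Before modeling, the
covariate set is screened for collinearity: while any pair has Pearson
`|r| >= 0.7` over segments, the lower-priority member of the worst pair
is dropped. The default priority places ecologically interpretable
variables (ranch distance, NDVI summaries, terrain, stocking rate) ahead
of the geographic proxies, so a vegetation-structure variable collinear
with latitude survives and latitude is dropped — the behavior a field
analyst would choose.

# The count GAM

`fit_dsm()` fits the offsetted count model with `mgcv`: one cubic
regression spline per covariate (`k = 10`), REML smoothness selection,
and the *shrinkage* variant of the basis (`bs = "cs"`), whose penalty
also acts on the null space of the second-derivative penalty. This lets
a term's effective degrees of freedom fall below 1, effectively removing
covariates the data do not support. We use the shrinkage-basis
construction rather than the two-penalty alternative because it is the
classical shrinkage-smoother formulation, it is what the field's DSM
tooling defaults to, and in our prototyping it shrank pure-noise terms
harder (edf < 0.5 in roughly 79% vs 62% of fits at survey scale) at no
cost in power.

Three response families handle the overdispersed, zero-heavy counts:

* **Tweedie** (`power p` in (1, 2), variance `phi mu^p`): `p` is profiled
  continuously by the same REML criterion used for the smoothing
  parameters, rather than over a fixed grid — the estimate is exact at
  the optimum rather than rounded to a grid point, and it is what the
  standard toolchain does.
* **Negative binomial**, theta estimated by REML.
* **Quasi-Poisson**, scale by the Pearson estimator; REML here is the
  extended-quasi-likelihood analog and is documented as an
  approximation.

**Term selection.** Backward stepwise at `alpha = 0.01`: the smooth with
the largest approximate Wald p-value at or above the threshold is
removed and the model refitted until all remaining terms are
significant. Stepwise removal is deterministic and reproducible; the
removal log is attached to the reduced fit. Concurvity (the smooth-term
analog of collinearity) is reported per term as the worst / observed /
estimate indices, all in [0, 1].

**Family choice.** The three reduced models are compared on
randomized-quantile residuals: exact CDF inversions for Tweedie (via an
in-package compound-Poisson-gamma series CDF) and the negative binomial,
scaled deviance residuals for quasi-Poisson. The family with the highest
QQ correlation against normal quantiles is selected; a configuration
override exists because residual judgment is ultimately the analyst's.

# Prediction and uncertainty

Abundance per 4 km^2 grid cell is `N_c = A_c exp(b0 + sum f_k(z_ck))`;
detectability was absorbed by the offset during fitting, so no `p`
appears at prediction. Cells are included by the mask value at their
center (no partial cells), and cells whose covariates lie outside the
fitted range are flagged as extrapolated but not blocked — surveys never
cover the full covariate range and the map must still be complete.

Variance uses the delta method on the spline coefficients, with the
coefficient covariance taken from the REML fit (which accounts for
smoothing-parameter uncertainty). Detection-function uncertainty is
propagated by refitting the model with an extra fixed column equal to
`d(-log p)/d theta` — the sensitivity of the offset to the detection
parameters — whose coefficient carries a zero-mean prior with covariance
equal to the detection-parameter covariance. Two implementation points
matter and are easy to get wrong:

* the prior is imposed through a fixed parametric penalty whose
  smoothing parameter must equal the estimated scale `phi`, because
  `mgcv` returns `(X'WX + sum sp S)^-1 phi` as the coefficient
  covariance;
* the derivative column is **zero** in the prediction matrix: abundance
  is a function of the spline coefficients alone, and the detection
  uncertainty reaches it through the posterior covariance between the
  extra coefficient and the intercept.

Both points are pinned by a parametric-bootstrap oracle in the test
suite (resample coefficients and the detection scale, recompute the
total; agreement within 20%). A documented fallback assumes independence,
`CV^2 = CV_gam^2 + CV_p^2`, and agrees closely with the refit when the
detection function has no covariates. With a uniform key there is no
detection parameter and the total CV equals the GAM CV exactly.
Intervals for abundance are log-normal,
`N * exp(+/- 1.96 sqrt(log(1 + CV^2)))`, the standard form for
distance-sampling estimates.

# Residual diagnostics

Because segments are nested in transects, residual autocorrelation is
summarized by a correlogram over lags in segment steps, pooling pairs
within transects and never across them. Deviance residuals are used —
defined for all three families. The approximate 95% band is
`+/- 2 / sqrt(m_l)` with `m_l` the pair count at lag `l`; simulation
shows the pooled lag-correlation estimator has standard deviation within
2% of `1 / sqrt(m_l)` under white noise, so the band is honest. No
correction for residual correlation is applied to the model itself; the
correlogram is a check that unmodeled correlation is small.

# The synthetic survey generator

The generator produces the study conditions the analysis assumes, at the
scale of a real Patagonian survey:

* **Landscape**: a 68 x 68 km projected extent at 500 m resolution with
  40 ranch buildings (sheep ranching divides such areas into tens of
  properties, one occupied building each); exact Euclidean
  distance-to-ranch; NDVI-like smooth Gaussian random fields (low-pass
  filtered noise) for vegetation and terrain covariates; a stocking-rate
  field; and a masked 4 km border strip standing in for unsurveyed
  coastal margins. The vegetation-CV field is constructed with an exact
  sample correlation (default 0.55, configurable) with latitude so the
  collinearity screen can be exercised at a known strength.
* **Population**: an inhomogeneous Poisson process with log-linear
  intensity in the covariates, realized by thinning a homogeneous
  process at the intensity supremum. Default effects: density rising
  `exp(2.2 exp(-d/2500 m))`-fold toward ranch buildings and
  `exp(1.2)`-fold from the extent center to the eastern edge. The
  intercept is solved so the mean intensity over the unmasked area is
  0.25 groups per km^2. Group sizes are zero-truncated negative binomial
  calibrated to mean 2.65 and SD 1.76 (a Poisson fallback exists); the
  ZTNB was chosen because it matches both printed moments while
  permitting overdispersion.
* **Transects**: systematic parallel lines with a random origin, spread
  across the full unmasked width subject to a 1 km minimum separation,
  with the last line shortened so the requested total (default
  1,085.4 km) is met exactly. Lines are placed inside the unmasked study
  area: the masked border is unsurveyed habitat and surveying it would
  dilute the encounter rate the defaults are calibrated to.
* **Detection**: each group within the 500 m strip of its nearest
  transect is detected with probability `g(y)` at its exact
  point-to-segment distance, independently of group size (the platform
  is treated as a single detector, and the constant-`p` count method
  makes group-level detection the consistent choice). The default
  half-normal scale of 185 m puts the 90th percentile of detected
  distances near 304 m, and together with the 0.25 groups/km^2 intensity
  yields an encounter rate of about 0.11 sightings per km and roughly
  115-120 sightings per survey.

These defaults were calibrated once, by forward simulation against the
published anchors (encounter rate, group-size moments, truncation
distance, and the significance structure of the retained covariates),
and then frozen. What the generator does **not** emulate: animal
movement and double-counting, den structure and breeding aggregation,
observer-specific detection heterogeneity, distance-measurement error,
and the spatial autocorrelation of real vegetation indices beyond
smooth-field structure. Passing recovery tests on this generator
therefore shows the estimator chain is correct under its own
assumptions, not that those assumptions hold in any particular field
dataset.

For recovery tests the package simulates segment counts directly from a
Tweedie process with `p = 1.4` and `phi = 5.2`; the dispersion comes
from matching the count variance-to-mean ratio to the compound-Poisson
value `E[S^2]/E[S] ~= 3.8` implied by the group-size moments above.

# Problem sizes used in the tests

Recovery tests run at the survey's own scale: 603 segments of 1.8 km,
~107 retained sightings, a ~3,600 km^2 prediction grid of 4 km^2 cells,
100 replicates for interval coverage and term selection, 200 bootstrap
draws for the variance oracle, and 200 correlogram replicates. These
sizes give Monte-Carlo standard errors comfortably below the tolerances
being asserted while keeping the whole suite around two minutes.

# Using real deposited segment data

`read_segment_table()` loads an externally prepared per-segment CSV
(effort, counts, covariates) so the DSM stage can be run on published
supplementary data rather than simulation; supply the published
truncation distance via `w_m` and the published detectability through an
explicit offset or a manually constructed detection fit. The test suite
exercises this path with a synthetic stand-in table whose truth is
known; reproducing a published Table-2-style row end-to-end additionally
requires the original deposited files and the exact masked grid
geometry, which are not redistributed with the package.

# Known limitations

* Detection covariates (observer, weather, group size) are out of scope;
  the API reserves no slot for them beyond refitting with a different
  offset.
* Quasi-Poisson REML is an extended-quasi-likelihood analog, not a true
  restricted likelihood.
* Per-cell CVs are cell-wise; no spatial covariance between cells is
  reported in the maps.
* Affine rescaling of covariates changes fitted values only within the
  tolerance of the REML smoothing-parameter search (about 1% on
  aggregate abundance), not exactly.
* The segment-boundary assignment rule and midpoint covariate sampling
  are deterministic conventions; strip-averaged covariate sampling is
  available behind a configuration flag only as future work.
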
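---
title: "Methods: movement, water-column, and isotope models in aslforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement, water-column, and isotope models in aslforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aslforage)
```

This vignette documents the models behind each stage of the pipeline,
the default parameter values and why they were chosen, and the scope and
limits of the synthetic-data generators used for validation.

## Geometry

All movement computations run in a local azimuthal-equidistant plane
(`project_local()`) centred on the track: distances from the origin are
exact great-circle distances, and pairwise distortion within the ~300-km
extent of a foraging range is below 0.1%. Great-circle distances use the
haversine formula with a 6371.0088-km mean Earth radius. Gridded fields
use a minimal ESRI ASCII reader/writer (`read_esri_ascii()` /
`write_esri_ascii()`) and Horn's eight-neighbour finite-difference slope
(`grid_slope()`).

## Track processing

- **Class filtering.** ARGOS location class Z carries no position
  estimate and is dropped (`drop_unclassified()`). Duplicate timestamps
  keep the better class, ties keep the first record (`dedup_fixes()`).
- **Speed filter.** `speed_filter()` implements the McConnell (1992)
  root-mean-square filter: a fix is removed while the rms of its
  adjacent-segment speeds exceeds `vmax`, iterating to convergence.
  Default `vmax = 2` m/s, the sustained-swim bound for otariids. The
  paper's phrase "moving average of 2 m/s" is read as this cited filter,
  not a smoothing window.
- **Interpolation.** `interpolate_track(mode = "ctcrw")` fits a
  continuous-time correlated random walk (Johnson et al. 2008): an
  Ornstein–Uhlenbeck velocity process integrated into position, with
  per-location-class observation noise, estimated by maximum likelihood
  and smoothed with a Kalman/RTS pass. A linear mode is the documented
  fallback when the optimizer fails. Default grid spacing 2 h.
- **Trips.** `segment_trips()` cuts the raw wet/dry record at the
  observed transitions; a trip must be *strictly* longer than 6 h at sea
  (a 6.0-h bout is excluded). Boundaries snap to raw transition times,
  not the interpolation grid.

## First-passage time and the ARS scale

`rediscretize()` converts a trip to exact 1-km Euclidean steps by
walking the polyline and solving the segment–circle crossing from the
last placed point; consecutive spacing is 1 km to within 1e-6 and a
sub-step tail is dropped. This matters on tortuous paths, where
arc-length marking would place points closer than 1 km.

`first_passage_time()` computes, for every path point, the time for the
animal to cross a circle of radius *r* forwards plus backwards, with the
crossing instant solved in closed form (quadratic in the segment
parameter); points whose circle is never exited are `NA`. The test suite
checks it against an independent root-finding oracle to 1e-6 h.

`ars_scale()` sweeps radii on a log grid from `r_min = 0.5` km to twice
the maximum daily step length and takes the ARS scale at the peak of
var(log FPT) (Fauchald & Tveraa 2003). The natural log is used
throughout; var(log FPT) is invariant to uniform time rescaling, so the
scale does not depend on travel speed. A profile with
`varlog_max < 0.01` is flagged non-informative (straight transit).
`label_ars()` flags points above the `q = 0.75` FPT quantile at the ARS
scale — the upper quartile separates dwelling from transit without
assuming a parametric mixture.

## Brownian-bridge utilization distributions

`estimate_bm_variance()` maximizes the Horne et al. (2007) leave-one-out
likelihood: every second location is predicted by the Brownian bridge
between its neighbours, with variance
*T*α(1−α)σ² + (1−α)²δ₁² + α²δ₂² + δ_mid², i.e. including the observed
midpoint's own location-error term (exact likelihood; identical to the
textbook form when δ = 0). `bbmm_ud()` integrates the bridge by midpoint
quadrature in time on a planar grid (default 1-km cells, 3σ halo);
masses are normalized to 1. `ud_areas()` reports the smallest set of
cells containing 50%/95% of the mass; areas are cell count × cellsize²
in the projected plane. Grids are planar km rather than geographic cells
— equivalent to evaluating cell area at the grid-centre latitude, but
exact.

## Water-column structure

`sigma_theta()` implements the EOS-80 (UNESCO 1983) one-atmosphere
equation of state; the published check values (σθ(35, 25) = 23.34306,
σθ(35, 5) = 27.67547 kg m⁻³) are frozen into the tests. An `eos`
function argument provides the hook for a TEOS-10 implementation; no
TEOS-10 library is available in this environment, so the EOS-80 route is
the shipped default.

`mixed_layer_depth()` uses the Δσθ = 0.125 kg m⁻³ threshold against a
4-m reference level, linearly interpolating the crossing depth between
bottle levels; a fully mixed cast returns the deepest level.
`thermocline_intensity()` is the maximum σθ gradient;
`benthic_and_transition()` reports bottom-level properties and the
thickness of the layer between the mixed layer and the bottom.
`classify_upwelled()` applies the strict subsurface criteria
T < 17 °C *and* σθ > 26 kg m⁻³ *and* S < 35.6 (all strict: a value
exactly at a threshold is not flagged). Monthly fields are gridded by
inverse-distance weighting (power 2, 100-km search radius).

## Habitat residency (Cox proportional hazards)

The FPT at the ARS scale is treated as a residency duration and its
"leaving rate" modelled with a Cox proportional-hazards model authored
from first principles: Newton–Raphson on the Breslow partial likelihood
(reverse cumulative sums over the risk sets), cluster-robust sandwich
standard errors with trips as clusters, and AICc with the number of
events as the sample size. Candidate sets are screened for collinearity
by pairwise Pearson |r| > 0.7 before enumeration (`pearson_screen()`,
`cox_select()`). Coefficients exceeding |β| = 20 abort with a
complete-separation error — the score under separation decays like
e^(−β), so without the guard Newton–Raphson would silently "converge"
at a meaningless β ≈ 22. The suite cross-checks coefficients, robust
SEs, and log-likelihoods against `survival::coxph` and an exhaustive
grid-search oracle.

## Whisker isotopes and seasonal ARIMA

`segment_timeline()` dates 3-mm whisker segments using a 3 mm/month
growth rate, with the base segment newest. `compare_individuals()` runs
Kruskal–Wallis on per-animal series and Bartlett's test on their
variances. `sarima_fit()` delegates estimation to
`stats::arima(method = "CSS-ML")` — exactly the conditional-sum-of-
squares-then-ML procedure of the Box–Jenkins workflow — while the BIC
(−2ℓ + k·ln n_eff), the model search (`sarima_select()`), and the
Ljung–Box statistic are authored in the package. The default seasonal
search space is s ∈ {3, 4, 6, 12} months (quarterly to annual): a full
s ∈ 3..12 sweep multiplies the fit count several-fold without adding
periodicities that are interpretable on a monthly whisker timeline.

## Synthetic-data generators: scope and limits

Every generator returns both observations and the noise-free truth:

- `simulate_tracks()` — a central-place forager alternating haulout and
  trip phases, travelling at ~5 km/h to an offshore patch, performing
  slow ARS movement inside it, and returning; ARGOS errors are
  two-dimensional Gaussian with class-dependent scales and a realistic
  class mix; wet/dry follows the behavioural state. It does **not**
  model haulout-site switching, tidal gaps in ARGOS coverage, or
  autocorrelated error.
- `simulate_bathymetry()` — a smooth shelf ramp plus seeded bumps;
  adequate for slope/depth covariates, not for canyon-scale terrain.
- `simulate_ctd_profiles()` — a seasonally varying mixed layer over a
  stratified interior, with a bottom-trapped cold, dense plume in the
  upwelling season (austral summer); truth records the exact mixed layer
  depth and which levels are plume water. Casts shallower than 6 m are
  rejected.
- `simulate_isotope_series()` — a seasonal AR model
  (1 − φB)(1 − φ_s B^s) x_t = ε_t around a mean; stationarity of the
  requested parameters is enforced.

These generators exist to validate method code against known truth;
they are deliberately simple and are not calibrated to reproduce any
particular deployment.

## Reproducibility

`run_pipeline(config, seed, out_dir)` executes every stage and writes
all artifacts plus a JSON manifest; the same seed yields byte-identical
files. `scripts/acceptance.R --seed S --out F` recomputes the headline
quantities, deriving all sub-seeds from S. The numbered scripts under
`analysis/` walk the same pipeline as a narrative, one stage per script.
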
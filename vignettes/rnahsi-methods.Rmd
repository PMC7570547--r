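---
title: "Road-network-adjusted settlement-index population mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Road-network-adjusted settlement-index population mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnahsi)
```

## The problem and the model

Census populations are reported per administrative zone; many urban
questions need them on a fine grid. Dasymetric mapping redistributes zone
counts using an ancillary surface that is believed proportional (or
monotonically related) to where people actually are. This package builds
that surface from three layers on a common analysis grid (nominally 100 m,
projected CRS in metres):

1. **Nighttime light.** Raw digital numbers are converted to radiance with
   the sensor's absolute calibration, $L = 10^{-10}\,\mathrm{DN}^{3/2}$
   (W m⁻² sr⁻¹ µm⁻¹), then min–max normalised *within the study area* to
   $LJ_{nor} \in [0,1]$.
2. **Vegetation.** A year of EVI scenes (nominally 23) is reduced per cell
   to its maximum, $EVI_{max}$ — the standard cloud-removal composite.
   Negative values (water, bare rock) are clamped to 0 by default.
3. **Roads.** Each of six functional classes is turned into a kernel
   density surface (length of road per unit area); a PCA over the zone-level
   class sums yields class weights, and the weighted overlay is the
   composite road-network density $RND$.

The settlement index and its adjusted form are

$$HSI=\frac{1-EVI_{max}+LJ_{nor}}{(1-LJ_{nor})+EVI_{max}+LJ_{nor}\,EVI_{max}},
\qquad RNAHSI = HSI \cdot RND^{\,b}.$$

$HSI$ is large where light is strong and vegetation sparse. Its weakness as
a population proxy is structural: light misses people where activity is
underground, unlit, or compressed into dense low-light fabric, and light
blooms beyond its sources. Road density carries exactly the complementary
signal, and the exponent $b$ ties it to the census: a log–log OLS of
zone-level census density (persons/km²) on zone-level mean $RND$ fits
$\text{density} = a\,RND^{\,b}$. Zones with non-positive density or road
density are dropped from the fit (the logarithm is undefined there) and
counted in the fit report.

Zonal sums of the index are then calibrated linearly against the census
(ordinary least squares), the calibrated map is rescaled by the correction
factor (census total divided by estimated total), and accuracy is assessed
per zone:

$$MRE = \frac{100}{n}\sum_i \frac{|PE_i-P_i|}{P_i},\qquad
\%RMSE = 100\,\frac{\sqrt{\sum_i (PE_i-P_i)^2/n}}{\bar P}$$

plus $R^2$. The assessment accepts any aligned population raster, so an
external gridded product can be compared on the same zones.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| radiance exponent | 3/2 | – | the published DN→radiance calibration of the high-resolution NTL sensor; exposed because conventions differ between products |
| KDE kernel | quartic (biweight) | – | the common GIS line-density convention; unit volume, so grid total × cell area ≈ line length |
| KDE bandwidth | 3000 | m | chosen where the bandwidth sweep (100–5000 m at 100 m steps) shows high, stable census correlation across classes; the sweep object also reports the mean-r maximiser |
| sample spacing | cell/4 | m | polylines are discretised to length-weighted midpoints; the kernel sum converges to the exact line integral at O(spacing²) |
| HSI `eps` | 1e-9 | – | the HSI denominator vanishes at $(LJ_{nor},EVI_{max})=(1,0)$; it is floored at `eps` (see below) |
| disaggregation mode | regression | – | see below |
| density unit | persons / 0.01 km² | – | one 100 m cell is exactly 0.01 km², so the final density map is numerically the persons-per-cell map |

## Numerical choices

- **`eps` as a floor, not an addend.** The degenerate HSI denominator is
  handled as `max(denominator, eps)` rather than `denominator + eps`:
  regular cells are then computed exactly (the midpoint case
  $LJ_{nor}=EVI_{max}=0.5$ gives 0.8 to machine precision) while the
  degenerate corner stays finite at $2/\varepsilon$.
- **Nodata.** Missing cells are `NA` internally; any arithmetic involving
  them yields `NA`; the on-disk sentinel is only an I/O concern. Maximum
  compositing skips `NA` and returns `NA` only where every scene is
  missing. Bilinear resampling marks a target cell `NA` if any neighbour
  with non-zero interpolation weight is missing or outside the source
  lattice.
- **Cell-to-zone assignment** is by cell-centre containment (even-odd
  rule). Where zones overlap or a centre lies exactly on a shared boundary,
  the first zone in `zone_id` order wins — a documented, deterministic
  tie-break. In the synthetic scenes zone edges lie on cell edges, so no
  centre is ever on a boundary.
- **No KDE edge correction.** As in common GIS implementations, kernel mass
  falling outside the grid is simply lost; the mass-conservation property
  (grid total ≈ line length within 1%) therefore holds only for networks
  more than one bandwidth from the edge.
- **Regression-mode intercept.** The fitted intercept is spread uniformly
  over the in-area cells before the conservation rescale; negative
  predictions are clipped to zero first. Alternatives (`proportional`,
  `proportional_by_zone`) guarantee conservation at the study-area or zone
  level by construction; a zone with positive census but an all-zero index
  is spread uniformly with a warning.
- **Degenerate fits.** A constant response in the power-law or linear
  calibration has zero residuals; its $R^2$ is reported as 1. A zero-variance
  accuracy comparison has no defined Pearson correlation; `r_squared()`
  returns `NA` with a warning.
- **Census rounding.** Synthetic zone counts are `round()`ed per-zone
  integrals of the true density; the conservation invariant is stated on the
  rounded values (sum of counts equals the sum of per-zone rounded
  integrals).

## Open design points, and the choices made

- **PCA → weights.** No closed formula for turning a PCA of the zone×class
  density table into overlay weights is universally agreed. The package
  standardises columns, eigendecomposes the correlation matrix, retains
  components with eigenvalue ≥ 1 (Kaiser rule) and sets the raw weight of a
  class to the variance-weighted sum of its absolute loadings, normalised to
  sum to 1. Census population is *excluded* from the decomposition: the
  weights are meant to describe shared road-structure variance, not to
  double-dip the calibration target. Including it is a defensible
  alternative; it changes weights only marginally on the synthetic scenes.
- **Normalisation domain.** $LJ_{min}/LJ_{max}$ are taken over the study
  area (union of census zones), not the full scene, and the pipeline clips
  the normalised layer to the study area; normalising over the full scene
  and clipping afterwards would compress the in-area range.
- **Exponent reuse.** The power-law exponent is fitted on zone-mean RND and
  applied to per-cell RND in the same units. The exponent is unit-invariant;
  the coefficient is not, and is never reused across unit systems.
- **Line handling.** Discretised length-weighted sample points rather than
  exact per-segment kernel integrals: simpler, oracle-checkable, and the
  discretisation error is bounded and tested (the suite compares against a
  brute-force quadrature oracle at fine spacing, relative error ≤ 1e-6).

## What the synthetic city emulates — and what it does not

`generate_scene()` builds, from one integer seed (per-layer sub-streams, so
adding a layer never perturbs the others):

- an **attractiveness field** (mixture of Gaussian urban centres);
- **roads** as biased random walks that start stratified across the whole
  domain (street networks span a municipality; this also keeps every census
  zone road-served) and drift uphill, so dense areas get dense networks;
- **true density** = $a \cdot RND_{eq}^{\,b_{true}} + \text{floor}$, where
  $RND_{eq}$ is the equal-weight kernel density of the generated roads,
  $b_{true}=1.2322$ by default, and the floor (0.5 persons/km²) keeps every
  zone inhabited without flattening the log–log relation;
- **NTL** as the inverse radiance calibration of a *saturating* function of
  density (half-saturation 8000 persons/km² — light misses part of the
  activity over the densest fabric), Gaussian-blurred (blooming, σ = 260 m),
  multiplied by a smooth district-scale lognormal bias field (σ = 0.4,
  2 km correlation — lighting per inhabitant varies with land use and
  underground activity) and per-cell lognormal noise (σ = 0.1);
- an **EVI stack** decaying with density, modulated by an analogous smooth
  land-use field (σ = 0.3) with a seasonal cycle and per-scene jitter;
- **census zones** as a jittered rectangular partition (74 by default, the
  order of a large city's township count) with populations equal to rounded
  zonal integrals of the truth.

The degraded-NTL ingredients matter: with a noiseless, unblurred, unsaturated
NTL layer the settlement index alone is an almost perfect zonal predictor and
the road adjustment has nothing to add. The defaults are set to carry the
failure modes that motivate the adjustment.

What the generator does **not** emulate: street-grid topology (roads are
smooth walks, not networks), demographic micro-structure, mixed land use
within a cell, registration error between layers, and zone shapes more
irregular than rectangles. Passing tests on these scenes therefore show that
the pipeline recovers a road-linked density structure under realistic
degradation of the light signal — not that it reproduces any particular real
city's accuracy numbers.

## Problem sizes

The default scene is 200 × 200 cells at 100 m (a 20 km × 20 km city), 74
zones, 36 polylines, bandwidth 3000 m. The test suite runs the full
pipeline on 20 seeded scenes for the directionality check and uses 40 × 40
grids for oracle comparisons; the whole suite completes in under two
minutes on one CPU.

## Known limitations

- The ESRI ASCII raster interface carries the CRS only as a sidecar label;
  nothing is reprojected, and geographic (degree) rasters are rejected
  rather than handled.
- Pearson-based $R^2$ in the accuracy report is dominated by the largest
  zones; the identity-line variant (also reported) is the stricter measure
  when overall bias matters. Likewise %RMSE is dominated by the densest
  zones, and on synthetic scenes the two error metrics can rank two maps
  differently; MRE weights all zones equally.
- The regression disaggregation mode conserves the census total but not
  per-zone totals; use `proportional_by_zone` when zone-exact conservation
  is required.
- KDE volume is lost near grid edges (no boundary correction), biasing RND
  slightly low within one bandwidth of the edge.

## A minimal run

```{r example, eval = FALSE}
scene <- generate_scene(scene_params(seed = 42))
cfg <- validate_config(list(inputs = list(ntl = "in-memory",
                                          evi = "in-memory",
                                          roads = "in-memory",
                                          zones = "in-memory")))
res <- run_pipeline(cfg, scene = scene)
res$report
```
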
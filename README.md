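# rnahsi

Fine-scale urban population mapping from nighttime lights, vegetation and
road networks.

Census counts are published per administrative zone (township), which is far
too coarse for urban planning, emergency response or as a denominator layer
in spatial epidemiology. `rnahsi` redistributes those counts onto a 100 m
grid (dasymetric mapping) using a settlement index built from three widely
available layers:

- **NTL** — a nighttime-light raster in digital numbers (DN), converted to
  radiance by the sensor calibration `L = 10⁻¹⁰ · DN^(3/2)` and min–max
  normalised over the study area to `LJ_nor`;
- **EVI** — a stack of enhanced-vegetation-index scenes reduced to an annual
  maximum composite `EVI_max` (cloud removal);
- **RND** — road-network density: a quartic-kernel line density surface per
  road class (expressway, trunk, secondary trunk, branch, railway, other),
  combined with PCA-derived class weights.

The human settlement index and its road-network-adjusted variant are

    HSI    = (1 − EVI_max + LJ_nor) / ((1 − LJ_nor) + EVI_max + LJ_nor·EVI_max)
    RNAHSI = HSI · RND^b

where the exponent `b` comes from a log–log regression of zone-level census
density on zone-level mean road density (`density = a · RND^b`). The zonal
sums of RNAHSI are calibrated linearly against the census, the map is scaled
by a total-population correction factor, and accuracy is reported per zone
as MRE (mean relative error), %RMSE (RMSE divided by the mean zone
population) and R². NTL alone under-counts people where activity is unlit or
underground and over-counts where light blooms; the road-density adjustment
restores that signal, which is why RNAHSI beats the unadjusted HSI.

A seeded synthetic-city generator (`generate_scene()`) emulates all four
inputs with the statistical structure the method assumes, so the entire
pipeline is testable without any external download.

## Worked example

```r
library(rnahsi)

scene <- generate_scene(scene_params(seed = 42))
scene
#> <synthetic_scene> 200 x 200 cells @ 100 m, seed 42
#>   population 359,491 in 74 zones; 438.5 km of roads

cfg <- validate_config(list(inputs = list(ntl = "in-memory", evi = "in-memory",
                                          roads = "in-memory", zones = "in-memory")))
res <- run_pipeline(cfg, scene = scene)

res$power_fit
#> <power_law_fit> density = 1.115e+05 * RND^1.2103 (R^2 = 0.998, n = 74)
res$weights
#> <class_weights>
#>   branch           0.1830
#>   expressway       0.1367
#>   ...
res$report
#> <accuracy_report>
#>   MRE    42.78%
#>   %RMSE  78.54%
#>   R^2    0.807 (Pearson^2; identity-line 0.287)
#>   zones  74
```

The power fit recovers the exponent the scene was built with (1.2322, here
estimated 1.2103 from the rounded census), the PCA weights are near-uniform
because the synthetic road classes are laid down with the same statistics,
and the accuracy report shows the zone-level agreement of the final map.
Rerunning with `rnd_exponent = 0` in the config disables the road
adjustment and yields the HSI-only baseline, whose MRE is substantially
worse — the core claim of the method.

File-driven use is identical: write the scene with `scene_to_files()` (or
`rnahsi make-fixtures <dir> <seed>`), point a YAML config at the files and
call `run_pipeline("config.yaml")`, which writes the index, road-density,
population and density rasters plus the sweep table, PCA weights, power-fit
diagnostics, per-zone residuals and a run log.

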
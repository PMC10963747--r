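# fieldET

Field-scale **agricultural evapotranspiration** (ET) from a machine-learned
counterfactual of naturally-occurring ET, and the water-management analyses
built on top of it.

Monitoring irrigation withdrawals is a poor proxy for the water agriculture
actually *consumes*: only the evapotranspired share leaves the watershed.
Remote sensing gives total ET, but isolating the agricultural part requires
knowing what the same land would evapotranspire if fallow. This package
implements that counterfactual approach end to end:

$$\mathrm{ET}_{ag} = \mathrm{ET}_{tot} - \mathrm{ET}_{nat}$$

1. **Counterfactual model** — a gradient boosted regression-tree model of
   naturally-occurring ET, trained on fallow pixels (predictors: x, y,
   month, year, elevation, slope, aspect, topographic wetness index, soil
   quality, potential ET), with summer-outlier cleaning of the fallow set,
   a spatially blocked 60/10/30 split by 2 km squares, randomized
   hyperparameter search, and validation on annual sums over held-out
   blocks.
2. **Crop water intensity** — per-crop and per-group means of year-adjusted
   agricultural ET with spatially cluster-robust 95% CIs (sandwich over
   square tiles, G/(G−1) correction), variance decomposition by crop and
   covariates, and the empirical variogram that motivates the cluster size.
3. **Management scenarios** — per groundwater sub-basin, on single-year,
   orchard-filtered, covariate-adjusted values: crop switching to the
   median (and minimum) crop, capping high consumers at the crop median
   (farming practices), and fallowing the top-5% ET tail; regional
   aggregates are ET-weighted.
4. **Irrigation efficiency** — county agricultural-ET depth over irrigation
   depth (volume/area, mm/yr, two-year average policy), with a robustness
   sweep over year choices.

A **synthetic-landscape generator** with fully known ground truth (fields,
crops, orchard ages, counties, sub-basins, hidden natural-ET surface,
configured irrigation efficiencies) makes every stage testable offline;
it is first-class, tested code, not a fixture. Rasters are read and written
as GeoTIFF (uncompressed float64; bit-exact round trips), polygons as
GeoJSON, tables as CSV, configuration as YAML.

## Worked example

The analysis is organised as numbered drivers over the package functions;
run them in order from the repository root (outputs land under `results/`):

```sh
Rscript analysis/01_simulate.R            --seed 1
Rscript analysis/02_train_counterfactual.R --seed 1
Rscript analysis/03_agricultural_et.R      --seed 1
Rscript analysis/04_crop_statistics.R      --seed 1
Rscript analysis/05_scenarios.R            --seed 1
Rscript analysis/06_efficiency.R           --seed 1
```

With the default configuration (200 × 200 pixels at 70 m, 3 years, 6 crops,
15% fallow fields, noise SD 2.5 mm/month) and seed 1 this prints, among
other things:

```
fallow rows 198000; summer-outlier rule removed 825 pixel-years (cut 79.5 mm)
held-out annual R2 0.985, MAE 7.2 mm/yr over 3648 pixel-years
fallow-pixel mean ag ET -0.1 mm/yr (should be near 0)
overall mean ag ET 404.4 mm/yr (95% CI 385.3-423.5)
    group  mean ci_low ci_high n_pixels
1: ALMOND 628.1  590.4   665.7    28800
2:   CORN 320.4  310.3   330.5    10200
3:  GRAPE 452.6  447.1   458.0    29100
4: TOMATO 380.4  372.7   388.0    15600
5: WALNUT 547.7  506.2   589.3    12900
6:  WHEAT 145.4  136.8   154.0     6900
                 scenario savings_weighted_pct
1:         crop_switching                 21.3
2:       farming_practice                  5.6
3:              fallowing                  8.6
4: crop_switch_to_minimum                 65.8
   county_id ag_et_depth irrigation_depth_mm efficiency
1:         1       445.4              1110.8      0.401
2:         2       481.4               801.2      0.601
3:         3       477.8               594.5      0.804
4:         4       471.0               734.3      0.641
```

Reading these: the model explains 98.5% of annual natural-ET variance on
blocks it never saw, with 7.2 mm/yr mean absolute error; fallow test pixels
get ~0 agricultural ET, as they must. Estimated crop means sit on the
generator's configured increments (e.g. WHEAT 145 vs 150 mm/yr configured;
ALMOND is below its configured 700 because young orchards consume less).
Fallowing just 5% of land cuts 8.6% of consumption because it targets the
highest consumers, while switching every crop to the sub-basin median saves
21% — and to the minimum crop, 66% — mirroring the qualitative structure of
real-world results. County efficiencies recover the configured
0.4/0.6/0.8/0.65 almost exactly.

The same chain is available as one call:

```r
library(fieldET)
res <- run_pipeline(default_config(seed = 1), out_dir = "results/run1")
res$crop_means
```

## Repository layout

```
R/                  package code: grid/GeoTIFF/GeoJSON IO, synthetic
                    landscape, counterfactual, agricultural ET, spatial
                    statistics, scenarios, efficiency, pipeline
analysis/           numbered narrative drivers (01_simulate ... 06_efficiency)
scripts/acceptance.R  headline-quantity recomputation (JSON out)
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette: model, assumptions, design choices
```
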
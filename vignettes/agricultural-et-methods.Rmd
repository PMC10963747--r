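---
title: "Estimating agricultural evapotranspiration with a fallow-land counterfactual: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating agricultural evapotranspiration with a fallow-land counterfactual: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fieldET)
```

## The estimation problem

Irrigated agriculture raises evapotranspiration (ET) above what the same
land would evaporate and transpire if left fallow. That increase -
*agricultural ET* - is the water actually consumed by agriculture: it
leaves the watershed entirely, unlike withdrawals that return as runoff or
recharge. The package estimates it per pixel and year as

$$\mathrm{ET}_{ag} = \mathrm{ET}_{tot} - \mathrm{ET}_{nat},$$

where total ET is observed (remotely sensed in the real application,
simulated here) and naturally-occurring ET is a counterfactual: the ET the
pixel would show if fallow. The counterfactual is supplied by a gradient
boosted regression-tree model trained on pixels that actually are fallow,
using spatial coordinates, month, year, topography (elevation, slope,
aspect, topographic wetness index), soil quality, and potential ET (PET) as
predictors. Fallow land is the right training domain because it is the
management-relevant baseline: the difference predicts the water saved by
fallowing.

Key assumptions, inherited by everything downstream:

* fallow pixels span (or at least bracket) the covariate space of cropped
  pixels, so the model interpolates rather than extrapolates - the reason
  the generator intersperses fallow fields across the extent;
* the labelled fallow set is clean - enforced by the summer-outlier filter
  below;
* negative agricultural ET is model error, not physics; it is retained in
  all statistics (it is information) but never clipped except where a
  formula's literal form implies it.

## Training-set hygiene: the summer-outlier rule

Mislabelled active fields masquerade as fallow with implausibly high summer
ET. For each fallow pixel-year we sum ET over July-September and drop,
entirely (all twelve months), the pixel-years strictly above the 95th
percentile of those sums, pooled across years. Two conventions are fixed
package-wide and deliberately boring: percentiles always use linear
interpolation between order statistics (R type 7), and "top 5%" means
strict exceedance of the 0.95 quantile, so an all-ties input removes
nothing. The seasonal *sum* (rather than per-month screening) is used
because an actively irrigated field is high all season; the percentile and
the sum-vs-month choice are configurable
(`counterfactual$clean_percentile`).

## Spatially blocked validation

Nearby pixels are nearly identical, so random splits leak. Pixels are
grouped into 2 km-square blocks anchored at the grid origin and whole
blocks are assigned at random: 60% train, 10% validation, 30% test
(`round(fraction * n_blocks)` for the first two, remainder to test; 8180
blocks therefore give exactly 4908/818/2454). The validation partition
drives early stopping of the final fit; the test partition is touched only
by `validate_annual()`. Because the analyses run on yearly values, the
model is scored on yearly sums: predictions and observations are summed to
pixel-years (strict twelve-month rule) before computing $R^2$ and MAE, and
residual means are reported by block and by year to expose structured
error.

## The boosted-tree fit

`fit_counterfactual()` mirrors a randomized-search protocol: `n_candidates`
draws (default 100; desk-scale runs use 12-20) from a declared search space
(`eta`, `max_depth`, `subsample`, `colsample_bytree`, and a multiplier on
the minimum leaf size), scored by 3-fold CV RMSE on an unclustered
subsample (default 30,000 rows - the subsample size is a config knob
because nothing principled pins it), then a final refit on the full
training partition with early stopping against the blocked validation set
(cap 6000 rounds, patience 200). Two minimum-sample constraints - 200 to
split a node, 100 per leaf - collapse to a single `min_child_weight = 100`
under squared loss (a node under 200 cannot yield two children of 100);
the constraint scales proportionally with training-set size relative to a
reference of $10^7$ rows, so a 200k-row desk run uses a scaled floor of 2
and the search explores multiples of it. Everything is seeded; with one
thread the fit is bit-reproducible. Predictions are clipped below at zero:
an ET depth cannot be negative, and the model is silent on that constraint.

## What the synthetic landscape emulates - and what it does not

`generate_landscape()` + `generate_et_series()` build a fully known world:
a 200 x 200 pixel grid at 70 m (14 km extent), three years of monthly data,
contiguous 10 x 10-pixel rectangular fields (0.49 km^2, a large Central
Valley field), 15% of fields fallow by independent Bernoulli draws
(interspersed, not segregated - the counterfactual must interpolate), six
crops with area shares that favour water-intensive orchards, four counties
and eight rectangular groundwater sub-basins.

Natural ET is a month-modulated response surface: a seasonal soil-moisture
factor peaking in March (opposite the July PET peak - Mediterranean
rainfall is winter-dominant, so the fallow landscape is greenest in
spring), multiplying the sum of (i) a linear PET term, (ii)
saturating/threshold responses to TWI and to soil quality - the
shallow-water-table and soil-class effects that make fallow ET patchy in
real landscapes - plus their interaction, (iii) a gentle linear elevation
term, and (iv) a very-long-wavelength residual spatial trend. Gaussian
pixel-month noise (SD 2.5 mm, about 10% of the mean monthly natural ET of
~26 mm) is added and the result truncated at zero. Design choices worth
stating plainly:

* **TWI, slope, aspect and soils carry hillslope-scale texture** (random
  cosine surfaces with 1-10 cycles per domain) while elevation and PET are
  regionally smooth; PET in particular is nearly uniform in space because
  its real-world source is 0.1-degree data, coarser than the whole domain.
  Consequently the covariate space is sampled densely inside every 2 km
  block, which is what makes a fallow-trained model transferable - and is
  also true of real terrain indices.
* **Threshold-like covariate responses** (steep logistic in TWI and soil)
  are the regime where tree ensembles excel and a linear model underfits
  badly; the generator is explicitly designed so that the model class the
  pipeline uses can succeed, making the noiseless recovery check a test of
  the machinery rather than of an approximation gap. Smooth multiplicative
  PET-by-covariate interactions, by contrast, leave a spatially structured
  approximation residual that no amount of tuning removes at desk data
  volumes; real-world fits should therefore not be expected to reach the
  synthetic noiseless ceiling.
* **Agricultural increments are drawn per field-year**, not per pixel:
  `Normal(crop mean, within-crop SD)` truncated at zero, spread over
  April-October with a sinusoidal profile. Within-field pixels move
  together, which is what makes 2 km blocking (and field-scale clustering
  in the inference checks) meaningful. Young orchards (bearing fruit for
  5 years or less) draw from a mean scaled by 0.4.
* Crop means (700/600/450/380/320/150 mm/yr) and SDs (50-90 mm/yr) sit in
  the range reported for Central Valley crop groups; shares favour
  orchards so that, as in real sub-basins, the median crop is itself a
  high consumer and crop switching to the median saves much less than
  switching to the minimum.

What it does **not** emulate: soil-water-balance dynamics, weather
reanalysis, irrigation scheduling, crop rotation, California geography, or
spatially correlated *observation* noise. Passing the recovery tests
therefore demonstrates that the estimation machinery is correct and
well-calibrated under the stated statistical structure - not that real
OpenET-scale data meet that structure.

## Year adjustment and covariate control

Because the analyses are cross-sectional, year-level shifts are removed
first: `adjusted[p,y] = et[p,y] - (mean_y - grand mean)`. Every year's mean
then equals the grand mean exactly and within-year contrasts are untouched;
single-year input is a fixed point, which the scenarios (single-year by
construction) rely on. Before scenario evaluation, values are additionally
controlled to sample-average covariates: a pooled linear regression on
annual-mean PET, soil quality, TWI, elevation, aspect and slope, replacing
each value by residual + mean(fitted). Aspect is circular, so it enters as
sine and cosine by default (a raw-degrees option exists for literal
replication); a flag refits the control model within each sub-basin
instead of pooled (`scenarios$adjust_per_sub_basin`, default pooled - the
sub-basin evaluation already absorbs regional differences).

## Group means and spatially clustered inference

Point estimates of crop, crop-group and county means are per-group
arithmetic means - the dummy-regression identity. Standard errors use the
cluster sandwich over square spatial tiles anchored at the origin, with the
finite-cluster correction G/(G-1) (G = number of non-empty tiles) and 1.96
for the 95% CI; cluster counts in intended use are large, so the normal
quantile is appropriate, and a group observed in a single tile gets a
missing SE with a warning rather than a fake one. The tile side is 75 km at
real scale - chosen from the empirical variogram of agricultural ET, which
the package also computes (equal-width lag bins, pair subsampling with a
seed, semivariance = half the mean squared difference). On the 14 km
synthetic domain the configured tile is 2 km; the inference checks cluster
at the field scale, the correlation unit of the synthetic increment
process. The coverage experiment in the acceptance suite shows clustered
CIs at ~95% while iid CIs cover far less under spatially correlated noise -
the quantitative justification for clustering.

## Management scenarios

All four statistics are fractions of the sub-basin ET sum and are evaluated
on single-year, orchard-filtered, covariate-adjusted values (young and
exiting orchards would otherwise masquerade as low-consumption farming):

* **Crop switching**: every pixel's value is replaced by
  `min(crop mean, M)` with `M` the *median over distinct crop means* in the
  sub-basin - unweighted by area, the literal reading of a median over
  crops; linear interpolation applies for even counts.
* **Crop switching to the minimum**: same with the minimum crop mean - the
  land-cover-change ceiling.
* **Farming practices**: pixel values are capped at their crop's central
  consumption level in the sub-basin. The central statistic is the
  *median* by default (the descriptive texts say median; the formula
  symbol is an average) with `central = "mean"` available; the choice is
  recorded in the run manifest.
* **Fallowing**: pixels strictly above the sub-basin 0.95 quantile
  contribute zero. With `<=` on the boundary, an all-equal sub-basin saves
  nothing.

Negative values are retained in sums exactly as the formulas read (a
sensitivity flag floors them at zero). A sub-basin whose ET sum is
non-positive is flagged undefined and excluded from the regional aggregate,
which is ET-weighted - one minus pooled numerators over pooled baselines -
with the unweighted mean of fractions reported alongside, since printed
regional numbers could be read either way.

## Irrigation efficiency

Efficiency is agricultural ET over irrigation, both as county depths in
mm/yr: withdrawal volume divided by irrigated area (1 m^3 over 1 m^2 =
1000 mm), averaged over two reporting years by default (a drought and a
non-drought year in the real application; any year combination is
computable for the robustness sweep). All active agricultural land is
treated as irrigated; a county partially outside the study region has its
volume scaled by the in-region share of irrigated area, assuming irrigation
is evenly distributed. Where an irrigation source reports mass (teragrams),
conversion to volume assumes water density 1000 kg/m^3; the package works
volumetrically throughout. Efficiencies above 1 are reported but flagged -
they indicate inconsistent data, not physics. The synthetic irrigation
table is built by inverting this calculation at configured county
efficiencies, so the round trip is exact in the noiseless case and falls
inside the cluster-robust CI under noise.

## Numerical conventions and degenerate inputs

* Percentiles/quantiles: linear interpolation (type 7), everywhere.
* Ties at a cleaning or fallowing boundary: strict exceedance removes them
  from nothing ("top 5%" of an all-equal set is empty).
* Incomplete pixel-years: excluded from annual sums and counted (strict
  default); a partial mode exists for diagnostics only.
* Missing operands propagate as missing with counted messages; missing
  model features are an error naming the feature.
* Negative model predictions clip to zero; negative agricultural ET does
  not.
* GeoTIFFs are written as uncompressed little-endian float64 with
  ModelPixelScale/ModelTiepoint tags, so a write-read round trip is
  bit-exact and any standard reader can open them; NA is stored as NaN.
* All randomness flows from one run seed through fixed per-stage offsets;
  fits use one thread, making full runs byte-identical.

## Problem sizes

The default synthetic study is 200 x 200 pixels x 36 months (1.44 M
pixel-months, ~200k fallow training rows), sized so the full pipeline -
simulation, search, fit, prediction, inference, scenarios, efficiency -
completes in a few minutes on one CPU. The test suite runs reduced searches
(2-12 candidates) and smaller grids for unit checks while keeping the
default conditions for the recovery and coverage checks; the acceptance
script uses 12 search candidates on the default landscape.

## Known limitations

* The counterfactual is validated on fallow land only; transfer to cropped
  pixels rests on covariate overlap, which the generator enforces but real
  data need not.
* No pixel-level uncertainty is attached to predicted natural ET; CIs
  quantify sampling error of group means, not prediction error.
* The synthetic noiseless recovery ceiling (annual R^2 > 0.99) is a
  property of the threshold-response generator; smooth real-world response
  surfaces will sit lower, as the real-data headline numbers do.
* Scenario savings are upper bounds: within-crop variation attributed to
  practices also contains estimation error and unobserved land quality.
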
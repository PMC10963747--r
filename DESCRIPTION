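Package: fieldET
Title: Field-Scale Agricultural Evapotranspiration from Machine-Learned
    Natural-ET Counterfactuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates field-scale agricultural evapotranspiration (ET) as the
    difference between observed total ET and a machine-learned counterfactual of
    naturally-occurring ET, trained on fallow land with spatially blocked
    validation. Includes a fully specified synthetic-landscape generator with
    known ground truth, crop-level water-intensity estimation with spatially
    cluster-robust inference, three water-saving management scenarios evaluated
    per groundwater sub-basin, and county-level irrigation-efficiency accounting.
    Reads and writes GeoTIFF rasters, GeoJSON polygons and CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
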
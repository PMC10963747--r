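# Stage 3: agricultural ET = total - natural, annualized and year-adjusted.
#
# Joins the stage-2 natural-ET predictions to the observations, sums to
# pixel-years (strict 12-month rule), removes year-level shifts, and writes
# the annual pixel table plus one agricultural-ET GeoTIFF per year.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
ctx <- analysis_options()
cfg <- ctx$cfg
world <- simulate_world(cfg)
pm <- world$pm
g <- world$landscape$grid

pred <- fread(res_path(ctx, "counterfactual", "natural_et_predictions.csv"))
pm <- merge(pm, pred, by = c("pixel_id", "year", "month"), sort = FALSE)

annual <- annualize(pm)
adjusted <- year_adjust(annual)
say("annual pixels: %d rows over %d years; grand mean ag ET %.1f mm/yr",
    nrow(adjusted), uniqueN(adjusted$year), mean(adjusted$et_ag))
say("fallow-pixel mean ag ET %.1f mm/yr (should be near 0)",
    adjusted[land_cover == "FALLOW", mean(et_ag)])

fwrite(adjusted, res_path(ctx, "ag_et", "annual_pixels.csv"))

pxo <- world$landscape$pixels[, .(pixel_id, row_id, col_id)]
for (yr in cfg$years) {
  sl <- merge(adjusted[year == yr], pxo, by = "pixel_id")[order(row_id, col_id)]
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[cbind(sl$row_id + 1L, sl$col_id + 1L)] <- sl$et_ag
  write_geotiff(m, res_path(ctx, "ag_et", sprintf("et_ag_%d.tif", yr)),
                grid = g)
}
say("wrote %s/ag_et", ctx$results)
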
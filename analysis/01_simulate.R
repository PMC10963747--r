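# Stage 1: simulate the synthetic study region and write its layers.
#
# Produces, under <results>/sim/: covariate GeoTIFFs, one multi-band
# (band = month) total-ET GeoTIFF per year, county and sub-basin GeoJSON,
# the field/crop table, the county irrigation table, and - under
# <results>/sim/truth/ - the hidden natural-ET rasters and field-year
# increments that only tests and evaluation may consult.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
ctx <- analysis_options()
cfg <- ctx$cfg
world <- simulate_world(cfg)
ls <- world$landscape; ser <- world$series
g <- ls$grid

say("landscape: %d x %d pixels at %g m; %d fields (%d fallow)",
    g$n_rows, g$n_cols, g$pixel_size, nrow(ls$fields),
    ls$fields[land_cover == "FALLOW", .N])

as_mat <- function(v) matrix(v, g$n_rows, g$n_cols, byrow = TRUE)
pxo <- ls$pixels[order(row_id, col_id)]
for (cov in c("elevation", "slope", "aspect", "twi", "soil_quality")) {
  write_geotiff(as_mat(pxo[[cov]]), res_path(ctx, "sim", paste0(cov, ".tif")),
                grid = g)
}

pm <- ser$pixel_months[ls$pixels[, .(pixel_id, row_id, col_id)],
                       on = "pixel_id"]
for (yr in cfg$years) {
  a <- array(NA_real_, dim = c(g$n_rows, g$n_cols, 12L))
  a_nat <- a
  for (m in 1:12) {
    sl <- pm[year == yr & month == m][order(row_id, col_id)]
    a[, , m] <- as_mat(sl$et_tot)
    a_nat[, , m] <- as_mat(sl$et_nat)
  }
  write_geotiff(et_raster(a, g), res_path(ctx, "sim",
                                          sprintf("et_total_%d.tif", yr)))
  write_geotiff(et_raster(a_nat, g),
                res_path(ctx, "sim", "truth", sprintf("et_natural_%d.tif", yr)))
}
fwrite(ser$increments, res_path(ctx, "sim", "truth", "field_increments.csv"))
fwrite(ls$fields, res_path(ctx, "sim", "fields.csv"))
fwrite(generate_irrigation_table(ls, ser),
       res_path(ctx, "sim", "irrigation_table.csv"))

rect_table <- function(col) {
  out <- ls$pixels[, .(xmin = min(x) - g$pixel_size / 2,
                       xmax = max(x) + g$pixel_size / 2,
                       ymin = min(y) - g$pixel_size / 2,
                       ymax = max(y) + g$pixel_size / 2),
                   by = col]
  setnames(out, col, "id")
  out
}
write_geojson_rects(rect_table("sub_basin_id"),
                    res_path(ctx, "sim", "sub_basins.geojson"))
write_geojson_rects(rect_table("county_id"),
                    res_path(ctx, "sim", "counties.geojson"))

# round-trip integrity of the written rasters
stk <- read_raster_stack(res_path(ctx, "sim",
                                  sprintf("et_total_%d.tif", cfg$years[1])), g)
chk <- pm[year == cfg$years[1] & month == 1][order(row_id, col_id)]
stopifnot(identical(stk$values[, , 1], as_mat(chk$et_tot)))
say("wrote %s/sim (raster round trip verified)", ctx$results)
say("mean monthly total ET %.1f mm; fallow share of fields %.2f",
    mean(ser$pixel_months$et_tot),
    ls$fields[, mean(land_cover == "FALLOW")])
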
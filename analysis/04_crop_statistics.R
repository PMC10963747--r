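# Stage 4: crop water intensity with spatially clustered inference.
#
# Group means with cluster-robust CIs per crop and crop group, the share of
# variance explained by crop type (and additionally by climate/topography/
# soil covariates), and the empirical variogram that motivates clustering.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
ctx <- analysis_options()
cfg <- ctx$cfg
adjusted <- fread(res_path(ctx, "ag_et", "annual_pixels.csv"))
cl_m <- cfg$stats$cluster_m
cropped <- adjusted[land_cover != "FALLOW"]

overall <- group_mean_regression(adjusted, NULL, cl_m)
crop_means <- group_mean_regression(cropped, "land_cover", cl_m)
group_means <- group_mean_regression(cropped, "crop_group", cl_m)
say("overall mean ag ET %.1f mm/yr (95%% CI %.1f-%.1f)",
    overall$mean, overall$ci_low, overall$ci_high)
print(crop_means[, .(group, mean = round(mean, 1), ci_low = round(ci_low, 1),
                     ci_high = round(ci_high, 1), n_pixels)])

r2_crop <- variance_explained(cropped, grouping = "land_cover")
r2_full <- variance_explained(cropped, grouping = "land_cover",
                              covariates = c("pet_annual", "elevation",
                                             "aspect", "slope", "twi",
                                             "soil_quality"))
say("crop type explains %.1f%% of ag-ET variation; +covariates %.1f%%",
    100 * r2_crop, 100 * r2_full)

vario <- empirical_variogram(adjusted[year == max(cfg$years)],
                             max_lag_m = cfg$stats$variogram_max_lag_m,
                             n_bins = cfg$stats$variogram_bins,
                             max_pairs = cfg$stats$variogram_max_pairs,
                             seed = fieldET:::stage_seed(cfg, "variogram"))

fwrite(overall, res_path(ctx, "stats", "overall_mean.csv"))
fwrite(crop_means, res_path(ctx, "stats", "crop_means.csv"))
fwrite(group_means, res_path(ctx, "stats", "crop_group_means.csv"))
fwrite(data.table(r2_crop = r2_crop, r2_crop_covariates = r2_full),
       res_path(ctx, "stats", "variance_explained.csv"))
fwrite(vario, res_path(ctx, "stats", "variogram.csv"))
say("wrote %s/stats", ctx$results)
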
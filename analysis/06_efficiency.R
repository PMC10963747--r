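# Stage 6: county irrigation efficiency (agricultural ET over irrigation
# depth), with a robustness sweep over irrigation-year combinations.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
ctx <- analysis_options()
cfg <- ctx$cfg
adjusted <- fread(res_path(ctx, "ag_et", "annual_pixels.csv"))
irrigation <- fread(res_path(ctx, "sim", "irrigation_table.csv"))

irr_years <- cfg$efficiency$irrigation_years
if (is.null(irr_years)) irr_years <- head(sort(unique(irrigation$year)), 2)
eff <- compute_efficiency(adjusted, irrigation, years = irr_years,
                          cluster_m = cfg$stats$cluster_m)
say("irrigation years %s; county efficiencies:",
    paste(irr_years, collapse = "+"))
print(eff[, .(county_id, ag_et_depth = round(ag_et_depth, 1),
              irrigation_depth_mm = round(irrigation_depth_mm, 1),
              efficiency = round(efficiency, 3), flagged)])
say("configured efficiencies: %s",
    paste(cfg$landscape$county_efficiency, collapse = ", "))
fwrite(eff, res_path(ctx, "efficiency", "county_efficiency.csv"))

# robustness: every single-year choice
sweep <- rbindlist(lapply(sort(unique(irrigation$year)), function(yr) {
  e <- compute_efficiency(adjusted, irrigation, years = yr,
                          cluster_m = cfg$stats$cluster_m)
  e[, years_used := as.character(yr)]
  e
}))
fwrite(sweep, res_path(ctx, "efficiency", "county_efficiency_by_year.csv"))
say("wrote %s/efficiency", ctx$results)
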
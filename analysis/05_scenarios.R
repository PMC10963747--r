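# Stage 5: water-saving management scenarios per groundwater sub-basin.
#
# Single scenario year, young/exiting orchards removed, covariate-adjusted
# values, then the four scenarios: crop switching to the median crop,
# crop switching to the minimum crop, capping high consumers at the crop
# median (farming practices), and fallowing the top-5% ET tail.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
ctx <- analysis_options()
cfg <- ctx$cfg
world <- simulate_world(cfg)
adjusted <- fread(res_path(ctx, "ag_et", "annual_pixels.csv"))

scen <- run_scenarios(adjusted, cfg, crops = world$landscape$crops)
say("scenario year %d; orchard filter removed %d young + %d exiting pixels",
    scen$scenario_year, scen$orchard_report$n_young_removed,
    scen$orchard_report$n_last_year_removed)
print(scen$aggregate[, .(scenario,
                         savings_weighted_pct = round(100 * savings_weighted, 1),
                         savings_unweighted_pct = round(100 * savings_unweighted, 1),
                         n_undefined)])

fwrite(scen$by_sub_basin, res_path(ctx, "scenarios", "by_sub_basin.csv"))
fwrite(scen$aggregate, res_path(ctx, "scenarios", "aggregate.csv"))
say("wrote %s/scenarios", ctx$results)
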
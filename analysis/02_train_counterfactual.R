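# Stage 2: train the natural-ET counterfactual on fallow pixels.
#
# Fallow pixel-months are assembled, summer outliers removed, the data split
# into 2 km blocks (0.6/0.1/0.3), hyperparameters tuned by randomized
# search, and the model validated on annual sums over held-out blocks.
# Writes the monthly natural-ET predictions for all pixels plus validation
# tables under <results>/counterfactual/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
ctx <- analysis_options()
cfg <- ctx$cfg
world <- simulate_world(cfg)
pm <- world$pm

fallow <- assemble_training_table(pm)
cleaned <- clean_fallow_outliers(fallow, cfg$counterfactual$clean_percentile)
say("fallow rows %d; summer-outlier rule removed %d pixel-years (cut %.1f mm)",
    nrow(fallow), nrow(cleaned$removed), cleaned$threshold)

split <- block_split(cleaned$table, cfg$counterfactual$block_m,
                     cfg$counterfactual$fractions,
                     seed = fieldET:::stage_seed(cfg, "split"))
lab <- fieldET:::apply_split(cleaned$table, split)
say("blocks: %s", paste(names(attr(split, "realized")),
                        round(attr(split, "realized"), 3),
                        collapse = ", "))

model <- fit_counterfactual(lab[partition == "train"],
                            lab[partition == "validation"], cfg)
print(model)
metrics <- validate_annual(model, lab[partition == "test"],
                           cfg$counterfactual$block_m)
say("held-out annual R2 %.3f, MAE %.1f mm/yr over %d pixel-years",
    metrics$r2, metrics$mae_mm, metrics$n_pixel_years)

pm[, et_nat_hat := predict_natural_et(model, pm)]
fwrite(pm[, .(pixel_id, year, month, et_nat_hat)],
       res_path(ctx, "counterfactual", "natural_et_predictions.csv"))
fwrite(metrics$by_block, res_path(ctx, "counterfactual",
                                  "residuals_by_block.csv"))
fwrite(metrics$by_year, res_path(ctx, "counterfactual",
                                 "residuals_by_year.csv"))
fwrite(model$search, res_path(ctx, "counterfactual", "search_candidates.csv"))
fwrite(data.table(r2 = metrics$r2, mae_mm = metrics$mae_mm,
                  n_pixel_years = metrics$n_pixel_years,
                  best_iteration = model$best_iteration),
       res_path(ctx, "counterfactual", "validation_metrics.csv"))
say("largest absolute block-mean residual: %.1f mm/yr",
    metrics$by_block[, max(abs(mean_resid))])
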
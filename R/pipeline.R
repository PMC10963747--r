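`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-landscape analysis pipeline
#'
#' One call chains every stage: landscape + ET simulation, fallow training
#' table assembly and cleaning, spatially blocked split, hyperparameter
#' search and counterfactual fit, prediction of natural ET everywhere,
#' annualization and year adjustment, group-mean inference, variance
#' decomposition, variogram, the four management scenarios, and county
#' irrigation efficiency. Everything is driven by the `run_config` and its
#' seed; two runs with the same config are bit-identical.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param out_dir Optional directory; when given, result tables are written
#'   as CSV plus a JSON run manifest.
#' @param quiet Suppress progress messages.
#' @return A list of results (landscape, model, metrics, tables); see the
#'   pipeline sections in the methods vignette.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  validate_config(config)
  say <- function(...) if (!quiet) message(...)

  say("simulating landscape and ET series (seed ", config$seed, ")")
  landscape <- generate_landscape(config)
  series <- generate_et_series(landscape)
  pm <- pixel_month_table(landscape, series)
  pm <- merge(pm,
              landscape$fields[, .(field_id, orchard_years_bearing,
                                   last_year_flag)],
              by = "field_id", sort = FALSE)

  say("assembling and cleaning fallow training data")
  fallow <- assemble_training_table(pm)
  cleaned <- clean_fallow_outliers(fallow,
                                   config$counterfactual$clean_percentile)
  say("  removed ", nrow(cleaned$removed), " fallow pixel-years")

  split <- block_split(cleaned$table, config$counterfactual$block_m,
                       config$counterfactual$fractions,
                       seed = stage_seed(config, "split"))
  lab <- apply_split(cleaned$table, split)
  train <- lab[partition == "train"]
  val <- lab[partition == "validation"]
  test <- lab[partition == "test"]
  stopifnot(length(intersect(train$block_id, test$block_id)) == 0L,
            length(intersect(train$block_id, val$block_id)) == 0L,
            length(intersect(val$block_id, test$block_id)) == 0L)

  say("fitting counterfactual (", config$counterfactual$n_candidates,
      " candidates)")
  model <- fit_counterfactual(train, val, config)
  metrics <- validate_annual(model, test, config$counterfactual$block_m)
  say(sprintf("  held-out annual R2 %.3f, MAE %.1f mm/yr",
              metrics$r2, metrics$mae_mm))

  say("predicting natural ET and annualizing")
  pm[, et_nat_hat := predict_natural_et(model, pm)]
  ann <- annualize(pm)
  adj <- year_adjust(ann)

  # fallow pixels in held-out blocks: their agricultural ET should be ~0
  test_blocks <- split[partition == "test", block_id]
  adj[, block_id := tile_id(x, y, config$counterfactual$block_m)]
  fallow_test_mean <- adj[land_cover == "FALLOW" & block_id %in% test_blocks,
                          mean(et_ag)]

  say("group means, variance decomposition, variogram")
  cl_m <- config$stats$cluster_m
  cropped <- adj[land_cover != "FALLOW"]
  overall <- group_mean_regression(adj, NULL, cl_m)
  crop_means <- group_mean_regression(cropped, "land_cover", cl_m)
  group_means <- group_mean_regression(cropped, "crop_group", cl_m)
  r2_crop <- variance_explained(cropped, grouping = "land_cover")
  r2_crop_covariates <- variance_explained(
    cropped, grouping = "land_cover",
    covariates = c("pet_annual", "elevation", "aspect", "slope", "twi",
                   "soil_quality"))
  vg_year <- max(config$years)
  vario <- empirical_variogram(adj[year == vg_year],
                               max_lag_m = config$stats$variogram_max_lag_m,
                               n_bins = config$stats$variogram_bins,
                               max_pairs = config$stats$variogram_max_pairs,
                               seed = stage_seed(config, "variogram"))

  say("management scenarios")
  scen <- run_scenarios(adj, config, crops = landscape$crops)

  say("irrigation efficiency")
  irrigation <- generate_irrigation_table(landscape, series)
  irr_years <- config$efficiency$irrigation_years %||%
    utils::head(sort(unique(irrigation$year)), 2)
  eff <- compute_efficiency(adj, irrigation, years = irr_years,
                            cluster_m = cl_m)

  results <- list(
    config = config, landscape = landscape, series = series, model = model,
    split = split, cleaning = cleaned[c("removed", "exempt", "threshold")],
    metrics = metrics, annual = adj, overall = overall,
    crop_means = crop_means, group_means = group_means,
    r2_crop = r2_crop, r2_crop_covariates = r2_crop_covariates,
    fallow_test_mean = fallow_test_mean, variogram = vario,
    scenarios = scen, irrigation = irrigation, efficiency = eff)

  if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
  invisible(results)
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  fwrite(results$annual, p("annual_pixels.csv"))
  fwrite(results$overall, p("overall_mean.csv"))
  fwrite(results$crop_means, p("crop_means.csv"))
  fwrite(results$group_means, p("crop_group_means.csv"))
  fwrite(results$scenarios$by_sub_basin, p("scenarios_by_sub_basin.csv"))
  fwrite(results$scenarios$aggregate, p("scenarios_aggregate.csv"))
  fwrite(results$efficiency, p("efficiency.csv"))
  fwrite(results$variogram, p("variogram.csv"))
  fwrite(results$metrics$by_block, p("validation_residuals_by_block.csv"))
  fwrite(results$metrics$by_year, p("validation_residuals_by_year.csv"))
  fwrite(results$irrigation, p("irrigation_table.csv"))
  if (nrow(results$cleaning$removed) > 0)
    fwrite(results$cleaning$removed, p("cleaning_removed.csv"))
  manifest <- list(
    package = "fieldET",
    version = as.character(packageVersion("fieldET")),
    seed = results$config$seed,
    config = unclass(results$config),
    model = list(params = results$model$params,
                 best_iteration = results$model$best_iteration,
                 n_train = results$model$meta$n_train),
    validation = list(r2 = results$metrics$r2,
                      mae_mm = results$metrics$mae_mm),
    scenario_central_statistic = results$config$scenarios$central)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
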
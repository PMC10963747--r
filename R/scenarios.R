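# Shared bookkeeping for one sub-basin scenario evaluation: savings are
# 1 - numerator / baseline, undefined (NA) when the baseline ET sum is <= 0.
scenario_row <- function(sub_basin_id, scenario, numerator, baseline, n) {
  savings <- if (baseline > 0) 1 - numerator / baseline else NA_real_
  data.table(sub_basin_id = sub_basin_id, scenario = scenario,
             savings = savings, n_pixels = n,
             baseline_sum = baseline, numerator = numerator)
}

#' Crop-switching scenario: substitute high-ET crops with the median crop
#'
#' Every pixel's ET is replaced by `min(crop mean, M)` where `M` is the
#' median over the distinct crops' mean ET in the sub-basin (unweighted by
#' area, linear interpolation for even counts): growers of thirstier crops
#' switch to the sub-basin's median water-consuming crop.
#'
#' @param pixels data.table with `et_ag` (adjusted) and `crop` for one
#'   sub-basin.
#' @param sub_basin_id Identifier recorded in the result.
#' @return One-row data.table (see `scenario_row`).
#' @export
crop_switching_savings <- function(pixels, sub_basin_id = NA) {
  stopifnot(nrow(pixels) >= 1L)
  means <- pixels[, .(crop_mean = mean(et_ag)), by = crop]
  M <- median(means$crop_mean)
  dt <- merge(pixels, means, by = "crop", sort = FALSE)
  numerator <- sum(pmin(dt$crop_mean, M))
  scenario_row(sub_basin_id, "crop_switching", numerator, sum(pixels$et_ag),
               nrow(pixels))
}

#' Crop-switching floor: substitute every crop with the minimum crop
#'
#' Variant of the crop-switching scenario replacing the median crop mean
#' with the minimum crop mean: the upper bound of what land-cover change can
#' save without fallowing.
#'
#' @inheritParams crop_switching_savings
#' @export
crop_switch_to_minimum_savings <- function(pixels, sub_basin_id = NA) {
  stopifnot(nrow(pixels) >= 1L)
  means <- pixels[, .(crop_mean = mean(et_ag)), by = crop]
  M <- min(means$crop_mean)
  dt <- merge(pixels, means, by = "crop", sort = FALSE)
  numerator <- sum(pmin(dt$crop_mean, M))
  scenario_row(sub_basin_id, "crop_switch_to_minimum", numerator,
               sum(pixels$et_ag), nrow(pixels))
}

#' Farming-practice scenario: cap high consumers at their crop's central use
#'
#' Pixel ET above the crop- and sub-basin-specific central consumption level
#' is reduced to that level; land cover is unchanged. The central statistic
#' defaults to the median consumption level (`central = "mean"` gives the
#' literal average).
#'
#' @inheritParams crop_switching_savings
#' @param central `"median"` (default) or `"mean"`.
#' @export
farming_practice_savings <- function(pixels, sub_basin_id = NA,
                                     central = c("median", "mean")) {
  central <- match.arg(central)
  stopifnot(nrow(pixels) >= 1L)
  stat <- if (central == "median") median else mean
  caps <- pixels[, .(cap = stat(et_ag)), by = crop]
  dt <- merge(pixels, caps, by = "crop", sort = FALSE)
  numerator <- sum(pmin(dt$et_ag, dt$cap))
  scenario_row(sub_basin_id, "farming_practice", numerator,
               sum(pixels$et_ag), nrow(pixels))
}

#' Fallowing scenario: retire the top-ET tail of the sub-basin
#'
#' Pixels with ET strictly above the sub-basin `percentile` quantile (linear
#' interpolation) are fallowed (contribute zero); all others keep their ET.
#'
#' @inheritParams crop_switching_savings
#' @param percentile Quantile defining the retired tail (default 0.95, i.e.
#'   fallow the top 5% of lands).
#' @export
fallowing_savings <- function(pixels, sub_basin_id = NA, percentile = 0.95) {
  stopifnot(nrow(pixels) >= 1L)
  q <- as.numeric(quantile(pixels$et_ag, percentile, type = 7))
  contrib <- fifelse(pixels$et_ag <= q, pixels$et_ag, 0)
  scenario_row(sub_basin_id, "fallowing", sum(contrib), sum(pixels$et_ag),
               nrow(pixels))
}

#' Evaluate all four management scenarios per sub-basin and region-wide
#'
#' Enforces the scenario pipeline order: restrict to the single scenario
#' year, drop young/exiting orchards, adjust to sample-average covariates,
#' then evaluate each sub-basin. The region aggregate is ET-weighted:
#' `1 - sum(numerators) / sum(baselines)` over defined sub-basins (the
#' unweighted mean of sub-basin fractions is also reported).
#'
#' @param annual Annual pixel table (multi-year allowed; the scenario year
#'   is selected here).
#' @param config A `run_config` (central statistic, fallow percentile,
#'   scenario year options).
#' @param scenario_year Year to evaluate (default: the configured maximum).
#' @param crops Crop catalogue for the orchard filter.
#' @return list with `by_sub_basin` (per sub-basin x scenario), `aggregate`
#'   (per scenario: ET-weighted and unweighted savings, undefined-basin
#'   count) and `orchard_report`.
#' @export
run_scenarios <- function(annual, config = default_config(),
                          scenario_year = max(annual$year),
                          crops = default_crops()) {
  one <- annual[year == scenario_year]
  if (nrow(one) == 0L) stop("no rows for scenario year ", scenario_year)
  filt <- filter_orchard_age(one, crops)
  adj <- if (isTRUE(config$scenarios$adjust_per_sub_basin)) {
    rbindlist(lapply(split(filt$table, by = "sub_basin_id"),
                     covariate_adjust, value_col = "et_ag_adjusted"))
  } else {
    covariate_adjust(filt$table, value_col = "et_ag_adjusted")
  }
  dat <- adj[land_cover != "FALLOW",
             .(sub_basin_id, crop = land_cover, et_ag = et_ag_adjusted)]
  if (config$scenarios$floor_negative) dat[, et_ag := pmax(0, et_ag)]

  res <- rbindlist(lapply(split(dat, by = "sub_basin_id"), function(d) {
    sb <- d$sub_basin_id[1]
    rbind(crop_switching_savings(d, sb),
          farming_practice_savings(d, sb, config$scenarios$central),
          fallowing_savings(d, sb, config$scenarios$fallow_percentile),
          crop_switch_to_minimum_savings(d, sb))
  }))
  agg <- res[, .(
    savings_weighted = {
      ok <- !is.na(savings)
      if (any(ok)) 1 - sum(numerator[ok]) / sum(baseline_sum[ok]) else NA_real_
    },
    savings_unweighted = mean(savings, na.rm = TRUE),
    n_sub_basins = .N, n_undefined = sum(is.na(savings))), by = scenario]
  list(by_sub_basin = res, aggregate = agg, orchard_report = filt$report,
       scenario_year = scenario_year)
}
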
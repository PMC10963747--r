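#' County irrigation depth from volume and irrigated area
#'
#' Converts withdrawal volume over irrigated area to a depth
#' (1 m^3 over 1 m^2 = 1000 mm) and applies the year policy: by default the
#' average of the depths of the two configured years (an analog of using the
#' two most recent reporting years, one drought and one non-drought); any
#' single year or combination can be requested for robustness sweeps.
#'
#' @param records data.table with `county_id`, `year`, `volume_m3`,
#'   `area_m2`.
#' @param years Years to use; default all present (averaged).
#' @param in_region_fraction Optional table `county_id`,
#'   `in_region_fraction`: the share of a county's irrigated area inside the
#'   study region; volumes are scaled by it, assuming irrigation is evenly
#'   distributed over irrigated lands inside and outside.
#' @return data.table `county_id`, `irrigation_depth_mm`, `years_used`.
#'   Zero-area county-years yield a missing depth with a warning.
#' @export
irrigation_depth <- function(records, years = NULL,
                             in_region_fraction = NULL) {
  rec <- copy(as.data.table(records))
  if (!is.null(years)) rec <- rec[year %in% years]
  if (nrow(rec) == 0L) stop("no irrigation records for requested years")
  if (!is.null(in_region_fraction)) {
    rec <- merge(rec, as.data.table(in_region_fraction), by = "county_id",
                 all.x = TRUE)
    rec[!is.na(in_region_fraction),
        `:=`(volume_m3 = volume_m3 * in_region_fraction,
             area_m2 = area_m2 * in_region_fraction)]
  }
  zero <- rec[area_m2 <= 0 | is.na(area_m2)]
  if (nrow(zero) > 0)
    warning(nrow(zero), " county-year(s) with zero irrigated area; ",
            "depth set to missing")
  rec[, depth_mm := fifelse(area_m2 > 0, volume_m3 / area_m2 * 1000,
                            NA_real_)]
  rec[, .(irrigation_depth_mm = mean(depth_mm),
          years_used = paste(sort(unique(year)), collapse = "+")),
      by = county_id]
}

#' County irrigation efficiency: agricultural ET over irrigation depth
#'
#' Efficiency is the proportion of withdrawn irrigation water that becomes
#' agricultural ET. Per county, agricultural-ET depth is the mean adjusted
#' agricultural ET over cropped pixels (all active agricultural land treated
#' as irrigated), with a cluster-robust CI; irrigation depth comes from
#' [irrigation_depth()]. Values above 1 are permitted but flagged - they
#' signal inconsistent data, not super-unity physics.
#'
#' @param annual Annual pixel table (cropped and fallow pixels; fallow rows
#'   are excluded here).
#' @param irrigation Irrigation record table (see [irrigation_depth()]).
#' @param years Irrigation years to use (default: all in `irrigation`).
#' @param cluster_m Cluster size for the ag-ET CI.
#' @param value_col Adjusted agricultural-ET column.
#' @param in_region_fraction See [irrigation_depth()].
#' @return data.table per county: `ag_et_depth`, `se`, `ci_low`, `ci_high`,
#'   `irrigation_depth_mm`, `efficiency`, `flagged`, `years_used`. Counties
#'   absent from the irrigation table keep a missing efficiency.
#' @export
compute_efficiency <- function(annual, irrigation, years = NULL,
                               cluster_m = 2000,
                               value_col = "et_ag_adjusted",
                               in_region_fraction = NULL) {
  cropped <- annual[land_cover != "FALLOW"]
  if (nrow(cropped) == 0L) stop("no cropped pixels")
  est <- group_mean_regression(cropped, "county_id", cluster_m, value_col)
  setnames(est, c("group", "mean"), c("county_id", "ag_et_depth"))
  est[, county_id := as.integer(county_id)]
  dep <- irrigation_depth(irrigation, years, in_region_fraction)
  out <- merge(est, dep, by = "county_id", all.x = TRUE)
  out[, efficiency := ag_et_depth / irrigation_depth_mm]
  out[!is.na(efficiency) & irrigation_depth_mm <= 0, efficiency := NA_real_]
  out[, flagged := !is.na(efficiency) & efficiency > 1]
  if (any(out$flagged))
    warning(sum(out$flagged), " county(ies) with efficiency > 1 (flagged)")
  out[]
}
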
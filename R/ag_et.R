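#' Agricultural ET as the total/natural difference
#'
#' The defining identity of the pipeline: agricultural ET is total observed
#' ET minus the natural-ET counterfactual. The signed difference is returned
#' without clipping; negative values carry information about counterfactual
#' error and are retained through all statistics.
#'
#' @param total,natural Numeric vectors (mm), recycled to a common length.
#' @return `total - natural`; missing operands yield missing results (a
#'   message reports the count).
#' @export
compute_ag_et <- function(total, natural) {
  out <- total - natural
  n_na <- sum(is.na(out))
  if (n_na > 0) message(n_na, " agricultural-ET values missing (NA operand)")
  out
}

#' Aggregate pixel-months to annual pixels
#'
#' Sums monthly values to pixel-years. By default (strict mode) pixel-years
#' missing any month are excluded and counted; `mode = "partial"` keeps
#' incomplete sums (useful only for diagnostics).
#'
#' @param pixels Pixel-month table with `et_mm` and (optionally) `et_nat_hat`
#'   monthly natural-ET predictions.
#' @param mode `"strict"` (default) or `"partial"`.
#' @return data.table with one row per pixel-year: `et_tot`, and when
#'   predictions were present `et_nat` and `et_ag`; static pixel attributes
#'   (land cover, memberships, covariates, annual-mean PET) are carried
#'   through. Attribute `"n_excluded"` counts dropped pixel-years.
#' @export
annualize <- function(pixels, mode = c("strict", "partial")) {
  mode <- match.arg(mode)
  has_nat <- "et_nat_hat" %in% names(pixels)
  static <- intersect(c("x", "y", "land_cover", "crop_group", "field_id",
                        "county_id", "sub_basin_id", "elevation", "slope",
                        "aspect", "twi", "soil_quality",
                        "orchard_years_bearing", "last_year_flag"),
                      names(pixels))
  ann <- pixels[, c(list(et_tot = sum(et_mm),
                         n_months = uniqueN(month),
                         pet_annual = if ("pet_mm" %in% names(pixels))
                           mean(pet_mm) else NA_real_),
                    if (has_nat) list(et_nat = sum(et_nat_hat)),
                    lapply(.SD, data.table::first)),
                by = .(pixel_id, year), .SDcols = static]
  n_excl <- 0L
  if (mode == "strict") {
    n_excl <- ann[n_months < 12L, .N]
    if (n_excl > 0)
      message(n_excl, " incomplete pixel-years excluded from annual table")
    ann <- ann[n_months == 12L]
  }
  ann[, n_months := NULL]
  if (has_nat) ann[, et_ag := compute_ag_et(et_tot, et_nat)]
  setattr(ann, "n_excluded", n_excl)
  ann[]
}

#' Remove year-to-year level shifts from annual agricultural ET
#'
#' Subtracts each year's deviation of the mean from the grand mean:
#' `adjusted[p, y] = et[p, y] - (mean_y - grand_mean)`. Afterwards every
#' year's mean equals the grand mean and all within-year contrasts are
#' untouched. Single-year input is a fixed point (the scenarios, which use
#' one year only, rely on this).
#'
#' @param annual Annual pixel table.
#' @param value_col Column to adjust (default `"et_ag"`).
#' @param out_col Name of the adjusted column (default `"et_ag_adjusted"`).
#' @return The table with `out_col` added (by reference-free copy).
#' @export
year_adjust <- function(annual, value_col = "et_ag",
                        out_col = "et_ag_adjusted") {
  if (nrow(annual) == 0L) stop("empty annual table")
  out <- copy(annual)
  grand <- mean(out[[value_col]])
  out[, yr_mean := mean(.SD[[1]]), by = year, .SDcols = value_col]
  out[, (out_col) := .SD[[1]] - (yr_mean - grand), .SDcols = value_col]
  out[, yr_mean := NULL]
  out[]
}

#' Drop young and exiting orchards before scenario analysis
#'
#' Orchards bearing fruit for 5 years or less consume much less water than
#' mature ones, and orchards in their last year of production are about to
#' leave the landscape; both are removed so scenario savings reflect
#' management, not stand age. Non-orchard crops pass through untouched;
#' orchard pixels lacking age attributes are retained with a warning.
#'
#' @param annual Annual pixel table with `land_cover`,
#'   `orchard_years_bearing`, `last_year_flag` and an `orchard` lookup via
#'   `crops`.
#' @param crops Crop catalogue (default [default_crops()]) identifying which
#'   codes are orchards.
#' @return list with `table` (filtered) and `report` (counts removed by
#'   reason, retained-with-warning count).
#' @export
filter_orchard_age <- function(annual, crops = default_crops()) {
  orch_codes <- crops[orchard == TRUE, crop]
  out <- copy(annual)
  is_orch <- out$land_cover %in% orch_codes
  age <- out$orchard_years_bearing
  last <- out$last_year_flag
  no_attr <- is_orch & is.na(age) & is.na(last)
  if (any(no_attr))
    warning(sum(no_attr),
            " orchard pixels lack age attributes; retained unfiltered")
  drop_young <- is_orch & !is.na(age) & age <= 5L
  drop_last <- is_orch & !is.na(last) & last %in% TRUE
  keep <- !(drop_young | drop_last)
  list(table = out[keep],
       report = data.table(n_young_removed = sum(drop_young),
                           n_last_year_removed = sum(drop_last & !drop_young),
                           n_missing_attr_retained = sum(no_attr),
                           n_kept = sum(keep)))
}
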
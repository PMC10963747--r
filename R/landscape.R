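#' Smooth random surface on a grid
#'
#' Sum of `n_modes` random cosine plane waves with frequencies between `fmin`
#' and `fmax` cycles per domain, rescaled to `[0, 1]`. Low frequencies give
#' regionally smooth fields (elevation, PET); higher frequencies give
#' hillslope-scale texture (TWI, slope, soils).
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param n_modes Number of cosine modes.
#' @param fmin,fmax Frequency range in cycles per domain extent.
#' @return Matrix `n_rows x n_cols` with values in `[0, 1]`.
#' @export
random_surface <- function(n_rows, n_cols, n_modes = 6L, fmin = 0.2,
                           fmax = 2) {
  rr <- matrix(seq_len(n_rows), n_rows, n_cols)
  cc <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  s <- matrix(0, n_rows, n_cols)
  for (k in seq_len(n_modes)) {
    theta <- runif(1, 0, 2 * pi)
    fr <- runif(1, fmin, fmax)
    fx <- fr * cos(theta) / n_cols
    fy <- fr * sin(theta) / n_rows
    ph <- runif(1, 0, 2 * pi)
    s <- s + rnorm(1) * cos(2 * pi * (fx * cc + fy * rr) + ph)
  }
  rng <- range(s)
  if (diff(rng) == 0) return(matrix(0.5, n_rows, n_cols))
  (s - rng[1]) / diff(rng)
}

#' Crop catalogue for a configuration
#'
#' The default catalogue, or the override supplied under
#' `config$landscape$crops` (any data.frame-like with the columns of
#' [default_crops()]).
#'
#' @param config A `run_config`.
#' @return data.table crop catalogue.
#' @export
landscape_crops <- function(config) {
  cr <- config$landscape$crops
  if (is.null(cr)) return(default_crops())
  cr <- as.data.table(cr)
  req <- c("crop", "crop_group", "mean_mm", "sd_mm", "orchard", "share")
  miss <- setdiff(req, names(cr))
  if (length(miss) > 0)
    stop("crops override missing column(s): ", paste(miss, collapse = ", "))
  cr
}

#' Generate a synthetic study landscape with known ground truth
#'
#' Builds the static part of the synthetic region: spatially smooth covariate
#' surfaces (elevation, slope, aspect, TWI, soil-quality index and a
#' potential-ET base surface), contiguous rectangular fields, fallow fields
#' interspersed among cropped ones by independent Bernoulli draws, orchard
#' age attributes, and rectangular county / groundwater sub-basin partitions.
#'
#' @param config A [default_config()]-style `run_config`.
#' @return An object of class `et_landscape`: list with `grid`, `pixels`
#'   (one row per pixel with coordinates, covariates and memberships),
#'   `fields` (one row per field with crop assignment and orchard
#'   attributes), `params` (the natural-ET function parameters), `crops`,
#'   and `config`.
#' @export
generate_landscape <- function(config = default_config()) {
  validate_config(config)
  set.seed(stage_seed(config, "landscape"))
  g <- et_grid(config$grid$origin_x, config$grid$origin_y,
               config$grid$pixel_size, config$grid$n_rows,
               config$grid$n_cols, config$grid$crs_label)
  nr <- g$n_rows; nc <- g$n_cols
  ls <- config$landscape

  # Covariates: elevation and PET vary regionally; TWI, slope, soils and
  # aspect carry hillslope-scale texture so that every 2 km block samples
  # the full covariate range (as real terrain indices do).
  elevation <- 500 * random_surface(nr, nc, 6L, 0.2, 1.5)
  slope     <- 10 * random_surface(nr, nc, 10L, 2, 10)
  twi       <- 2 + 10 * random_surface(nr, nc, 10L, 2, 10)
  soil      <- 100 * random_surface(nr, nc, 10L, 1, 8)
  aspect    <- 360 * random_surface(nr, nc, 10L, 2, 10)
  pet_base  <- 0.95 + 0.1 * random_surface(nr, nc, 6L, 0.2, 1)

  px <- pixel_centers(g)
  flat <- function(m) m[cbind(px$row_id + 1L, px$col_id + 1L)]
  px[, `:=`(pixel_id = .I,
            elevation = flat(elevation), slope = flat(slope),
            aspect = flat(aspect), twi = flat(twi),
            soil_quality = flat(soil), pet_base = flat(pet_base))]

  # Contiguous rectangular fields.
  fpr <- ls$field_rows; fpc <- ls$field_cols
  n_field_rows <- ceiling(nr / fpr); n_field_cols <- ceiling(nc / fpc)
  px[, field_id := (px$row_id %/% fpr) * n_field_cols + (px$col_id %/% fpc) + 1L]

  # Counties and sub-basins: equal rectangular partitions of the extent.
  px[, county_id := (px$row_id %/% ceiling(nr / ls$n_counties_y)) *
        ls$n_counties_x + (px$col_id %/% ceiling(nc / ls$n_counties_x)) + 1L]
  px[, sub_basin_id := (px$row_id %/% ceiling(nr / ls$n_subbasins_y)) *
        ls$n_subbasins_x + (px$col_id %/% ceiling(nc / ls$n_subbasins_x)) + 1L]

  crops <- landscape_crops(config)
  n_fields <- n_field_rows * n_field_cols
  fallow <- runif(n_fields) < ls$fallow_fraction
  if (all(fallow) || !any(fallow))
    stop("degenerate fallow draw: all or no fields fallow; ",
         "adjust fallow_fraction or field size")
  crop_draw <- sample(crops$crop, n_fields, replace = TRUE,
                      prob = crops$share)
  fields <- data.table(field_id = seq_len(n_fields),
                       land_cover = ifelse(fallow, "FALLOW", crop_draw))
  fields <- merge(fields,
                  crops[, .(land_cover = crop, crop_group, orchard)],
                  by = "land_cover", all.x = TRUE, sort = FALSE)
  setorder(fields, field_id)
  fields[is.na(orchard), orchard := FALSE]
  fields[, orchard_years_bearing := NA_integer_]
  fields[, last_year_flag := NA]
  n_orch <- fields[orchard == TRUE, .N]
  fields[orchard == TRUE,
         orchard_years_bearing := sample.int(ls$orchard_age_max, n_orch,
                                             replace = TRUE)]
  fields[orchard == TRUE,
         last_year_flag := runif(n_orch) < ls$last_year_prob]

  params <- list(
    # monthly PET cycle (mm/month) and its weak year trend
    pet_amp = c(base = 110, seasonal = 95), pet_year_slope = 0.02,
    # soil-moisture seasonality: peaks at the end of the wet season (March),
    # opposite the PET peak (July)
    moist = c(floor = 0.12, amp = 0.8, peak_month = 3, width = 10),
    # natural-ET response coefficients (see generate_et_series)
    beta = c(pet = 0.35, twi_hi = 20, twi_lo = 10, soil_hi = 16, soil_lo = 9,
             interaction = 5, elev = 0.004, trend_x = 0.3, trend_y = 0.25),
    thresholds = c(twi_hi = 7, twi_hi_scale = 0.2, twi_lo = 4.5,
                   twi_lo_scale = 0.25, soil_hi = 55, soil_hi_scale = 2,
                   soil_lo = 30, soil_lo_scale = 2, elev_ref = 400,
                   trend_wx = 20000, trend_wy = 25000),
    growing_months = 4:10,
    year_ref = stats::median(config$years)
  )

  structure(list(grid = g, pixels = px[], fields = fields[], crops = crops,
                 params = params, config = config),
            class = "et_landscape")
}

#' @export
print.et_landscape <- function(x, ...) {
  cat(sprintf(
    "<et_landscape> %s; %d fields (%d fallow), %d counties, %d sub-basins\n",
    format(x$grid), nrow(x$fields), x$fields[land_cover == "FALLOW", .N],
    uniqueN(x$pixels$county_id), uniqueN(x$pixels$sub_basin_id)))
  invisible(x)
}

# Monthly potential ET (mm/month) for pixels of a landscape.
pet_monthly <- function(landscape, pet_base, month, year) {
  p <- landscape$params
  cyc <- p$pet_amp[["base"]] +
    p$pet_amp[["seasonal"]] * cos(2 * pi * (month - 7) / 12)
  pmax(0, pet_base * cyc * (1 + p$pet_year_slope * (year - p$year_ref)))
}

# Seasonal soil-moisture multiplier; month-only.
moisture_factor <- function(landscape, month) {
  m <- landscape$params$moist
  m[["floor"]] + m[["amp"]] *
    exp(-((month - m[["peak_month"]])^2) / m[["width"]])
}

#' The hidden natural-ET response surface (truth access)
#'
#' Expected natural ET (mm/month, before noise) for rows carrying `month`,
#' `pet_mm`, `twi`, `soil_quality`, `elevation`, `x`, `y`: a month-modulated
#' sum of a linear PET term, saturating threshold responses to TWI and soil
#' quality (shallow-water-table and soil-class effects), their interaction,
#' a gentle elevation term and a very-long-wavelength residual spatial
#' trend. Exposed so that tests and truth outputs can compare against the
#' generator's ground truth; the estimation pipeline never reads it.
#'
#' @param landscape An `et_landscape`.
#' @param dt Table of pixel-month rows.
#' @return Numeric vector of expected natural ET (mm/month).
#' @export
natural_et_surface <- function(landscape, dt) natural_et_mean(landscape, dt)

# month-modulated natural-ET mean response (see natural_et_surface)
natural_et_mean <- function(landscape, dt) {
  p <- landscape$params; b <- p$beta; th <- p$thresholds
  moist <- moisture_factor(landscape, dt$month)
  inner <- b[["pet"]] * dt$pet_mm +
    b[["twi_hi"]] * plogis((dt$twi - th[["twi_hi"]]) / th[["twi_hi_scale"]]) +
    b[["twi_lo"]] * plogis((dt$twi - th[["twi_lo"]]) / th[["twi_lo_scale"]]) +
    b[["soil_hi"]] * plogis((dt$soil_quality - th[["soil_hi"]]) /
                              th[["soil_hi_scale"]]) +
    b[["soil_lo"]] * plogis((dt$soil_quality - th[["soil_lo"]]) /
                              th[["soil_lo_scale"]]) +
    b[["interaction"]] *
      plogis((dt$twi - th[["twi_hi"]]) / th[["twi_hi_scale"]]) *
      plogis((dt$soil_quality - th[["soil_hi"]]) / th[["soil_hi_scale"]]) +
    b[["elev"]] * (th[["elev_ref"]] - dt$elevation) +
    b[["trend_x"]] * sin(dt$x / th[["trend_wx"]]) +
    b[["trend_y"]] * cos(dt$y / th[["trend_wy"]])
  pmax(0, moist * inner)
}

# Growing-season monthly weights for spreading annual increments.
growing_season_weights <- function(landscape) {
  gm <- landscape$params$growing_months
  w <- sin(pi * (gm - min(gm) + 1) / (length(gm) + 1))
  setNames(w / sum(w), gm)
}

#' Simulate monthly total and natural ET over a landscape
#'
#' Natural ET is the hidden response surface plus iid Gaussian pixel-month
#' noise (truncated at zero: ET depths are non-negative). Total ET adds, on
#' cropped pixels only, the field-year agricultural increment spread over the
#' growing-season months. Increments are drawn once per field and year from
#' `Normal(crop mean, within-crop SD)` truncated at zero, so pixels of one
#' field move together; orchards flagged young (bearing fruit for 5 years or
#' less) draw from a mean scaled by `young_orchard_factor`.
#'
#' @param landscape An [generate_landscape()] result.
#' @param years Integer vector of years to simulate; defaults to the
#'   configured years.
#' @return Object of class `et_series`: list with `pixel_months` (pixel_id,
#'   year, month, pet_mm, et_nat, et_tot) and `increments` (field_id, year,
#'   increment mm/yr). `et_nat` is the hidden truth used only by tests and
#'   truth outputs.
#' @export
generate_et_series <- function(landscape, years = landscape$config$years) {
  if (length(years) == 0L) stop("years must be non-empty")
  cfg <- landscape$config
  set.seed(stage_seed(cfg, "series"))
  px <- landscape$pixels
  flds <- landscape$fields
  noise_sd <- cfg$landscape$noise_sd
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  # field-year increments
  crop_pars <- landscape$crops[, .(land_cover = crop, mean_mm, sd_mm)]
  inc <- CJ(field_id = flds$field_id, year = as.integer(years))
  inc <- merge(inc, flds, by = "field_id", sort = FALSE)
  inc <- merge(inc, crop_pars, by = "land_cover", all.x = TRUE, sort = FALSE)
  setorder(inc, field_id, year)
  young <- !is.na(inc$orchard_years_bearing) & inc$orchard_years_bearing <= 5L
  inc[, increment := 0]
  cropped <- inc$land_cover != "FALLOW"
  eff_mean <- inc$mean_mm
  eff_mean[young] <- eff_mean[young] * cfg$landscape$young_orchard_factor
  inc[cropped, increment := pmax(0, rnorm(sum(cropped), eff_mean[cropped],
                                          inc$sd_mm[cropped]))]
  increments <- inc[, .(field_id, year, land_cover, increment)]

  gw <- growing_season_weights(landscape)
  pm <- CJ(pixel_id = px$pixel_id, year = as.integer(years),
           month = 1:12, sorted = TRUE)
  pm <- merge(pm, px[, .(pixel_id, x, y, elevation, twi, soil_quality,
                         pet_base, field_id)],
              by = "pixel_id", sort = FALSE)
  pm[, pet_mm := pet_monthly(landscape, pet_base, month, year)]
  pm[, et_nat := natural_et_mean(landscape, pm)]
  if (noise_sd > 0)
    pm[, et_nat := pmax(0, et_nat + rnorm(.N, 0, noise_sd))]
  pm <- merge(pm, increments[, .(field_id, year, increment)],
              by = c("field_id", "year"), sort = FALSE)
  pm[, weight := 0]
  gm <- as.integer(names(gw))
  for (i in seq_along(gm)) pm[month == gm[i], weight := gw[[i]]]
  pm[, et_tot := et_nat + increment * weight]
  setorder(pm, pixel_id, year, month)
  out <- list(pixel_months = pm[, .(pixel_id, year, month, pet_mm,
                                    et_nat, et_tot)],
              increments = increments)
  class(out) <- "et_series"
  out
}

#' Assemble the full pixel-month observation table
#'
#' Joins the simulated ET series with pixel coordinates, covariates and land
#' cover into the flat table every downstream stage consumes: one row per
#' pixel and month with total ET as the observable and the predictor set
#' (x, y, month, year, elevation, slope, aspect, TWI, soil quality, PET).
#'
#' @param landscape An `et_landscape`.
#' @param series An `et_series` from [generate_et_series()].
#' @return data.table with one row per pixel-month (`et_mm` is observed total
#'   ET; the hidden `et_nat` is deliberately not included).
#' @export
pixel_month_table <- function(landscape, series) {
  px <- landscape$pixels
  fl <- landscape$fields[, .(field_id, land_cover, crop_group)]
  out <- merge(series$pixel_months,
               px[, .(pixel_id, x, y, elevation, slope, aspect, twi,
                      soil_quality, field_id, county_id, sub_basin_id)],
               by = "pixel_id", sort = FALSE)
  out <- merge(out, fl, by = "field_id", sort = FALSE)
  out[, et_mm := et_tot]
  setorder(out, pixel_id, year, month)
  out[, .(pixel_id, x, y, month, year, et_mm, land_cover, crop_group,
          field_id, county_id, sub_basin_id, elevation, slope, aspect, twi,
          soil_quality, pet_mm)]
}

#' Build the county irrigation table consistent with configured efficiencies
#'
#' For each county and year the irrigated area is the area of non-fallow
#' pixels and the withdrawal volume is the county's true agricultural-ET
#' volume divided by the configured efficiency, so that the efficiency module
#' recovers the configuration exactly in the noiseless case. Counties with no
#' cropped pixels get a zero-area row with missing volume.
#'
#' @param landscape An `et_landscape`.
#' @param series An `et_series` (its field-year increments are the truth).
#' @param years Years to tabulate; defaults to those in `series`.
#' @return data.table with `county_id`, `year`, `volume_m3`, `area_m2`.
#' @export
generate_irrigation_table <- function(landscape, series,
                                      years = unique(series$increments$year)) {
  eff <- landscape$config$landscape$county_efficiency
  px_area <- landscape$grid$pixel_size^2
  px <- merge(landscape$pixels[, .(pixel_id, field_id, county_id)],
              landscape$fields[, .(field_id, land_cover)],
              by = "field_id", sort = FALSE)
  out <- CJ(county_id = sort(unique(px$county_id)), year = as.integer(years))
  ag <- merge(px[land_cover != "FALLOW"],
              series$increments[, .(field_id, year, increment)],
              by = "field_id", allow.cartesian = TRUE, sort = FALSE)
  agg <- ag[, .(mean_depth_mm = mean(increment), n_px = .N),
            by = .(county_id, year)]
  out <- merge(out, agg, by = c("county_id", "year"), all.x = TRUE)
  out[, area_m2 := fifelse(is.na(n_px), 0, n_px * px_area)]
  out[, volume_m3 := (mean_depth_mm / 1000) * area_m2 /
        eff[county_id]]
  out[area_m2 == 0, volume_m3 := NA_real_]
  out[, .(county_id, year, volume_m3, area_m2)]
}
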
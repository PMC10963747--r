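# Shared fixtures: small configurations and hand-built tables.

small_config <- function(seed = 1L, n = 60L, years = c(2016L, 2017L),
                         field = 6L) {
  cfg <- default_config(seed)
  cfg$grid$n_rows <- as.integer(n)
  cfg$grid$n_cols <- as.integer(n)
  cfg$grid$origin_y <- as.integer(n) * cfg$grid$pixel_size
  cfg$years <- as.integer(years)
  cfg$landscape$field_rows <- as.integer(field)
  cfg$landscape$field_cols <- as.integer(field)
  cfg$counterfactual$n_candidates <- 2L
  cfg$counterfactual$cv_subsample <- 3000L
  cfg$counterfactual$cv_nrounds <- 40L
  cfg$counterfactual$nrounds <- 300L
  cfg$counterfactual$early_stopping_rounds <- 50L
  cfg$stats$variogram_max_pairs <- 20000L
  cfg
}

# A minimal pixel-month table with all model features, for unit tests that
# need observations but no landscape.
toy_pixel_months <- function(n_pixels = 10L, years = 2016L,
                             land_cover = "FALLOW") {
  dt <- data.table::CJ(pixel_id = seq_len(n_pixels), year = years,
                       month = 1:12)
  dt[, `:=`(
    x = pixel_id * 100, y = -pixel_id * 100,
    et_mm = 10 + month, land_cover = land_cover,
    elevation = 100, slope = 2, aspect = 180, twi = 6,
    soil_quality = 50, pet_mm = 50 + month)]
  dt[]
}

expect_tables_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
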
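test_that("agricultural ET is the signed, unclipped difference", {
  expect_equal(compute_ag_et(500, 120), 380)
  expect_equal(compute_ag_et(200, 200), 0)
  expect_equal(compute_ag_et(100, 150), -50)     # retained, not clipped
  expect_message(out <- compute_ag_et(c(1, NA), c(1, 1)), "1 agricultural")
  expect_true(is.na(out[2]))
})

test_that("annualization sums twelve months and applies the strict policy", {
  pm <- toy_pixel_months(2)
  pm[, `:=`(et_mm = 10, et_nat_hat = 4)]
  ann <- annualize(pm)
  expect_equal(ann$et_tot, c(120, 120))
  expect_equal(ann$et_nat, c(48, 48))
  expect_equal(ann$et_ag, c(72, 72))
  # incomplete pixel-years are excluded and counted; partial mode keeps them
  extra <- toy_pixel_months(1)[month <= 11][, pixel_id := 9L]
  extra[, `:=`(et_mm = 10, et_nat_hat = 4)]
  pm2 <- rbind(pm, extra)
  expect_message(ann2 <- annualize(pm2), "1 incomplete")
  expect_equal(nrow(ann2), 2L)
  expect_equal(attr(ann2, "n_excluded"), 1L)
  ann3 <- annualize(pm2, mode = "partial")
  expect_equal(nrow(ann3), 3L)
})

test_that("pixel-level linearity: sums of et_ag equal sum(tot) - sum(nat)", {
  set.seed(1)
  pm <- toy_pixel_months(20)
  pm[, `:=`(et_mm = runif(.N, 0, 50), et_nat_hat = runif(.N, 0, 40))]
  ann <- annualize(pm)
  expect_equal(sum(ann$et_ag), sum(ann$et_tot) - sum(ann$et_nat),
               tolerance = 1e-10)
})

test_that("year adjustment removes year means and fixes single years", {
  # year means 10 and 20 (grand 15); a pixel at 12 in year one becomes 17
  ann <- data.table::data.table(
    pixel_id = c(1, 2, 1, 2), year = c(1, 1, 2, 2),
    et_ag = c(12, 8, 22, 18))
  out <- year_adjust(ann)
  expect_equal(out[pixel_id == 1 & year == 1, et_ag_adjusted], 17)
  # conservation: every year's adjusted mean equals the grand mean
  expect_equal(out[, mean(et_ag_adjusted), by = year]$V1, c(15, 15))
  expect_equal(mean(out$et_ag_adjusted), mean(ann$et_ag))
  # within-year contrasts unchanged
  expect_equal(diff(out[year == 1]$et_ag_adjusted),
               diff(ann[year == 1]$et_ag))
  # single year is a fixed point
  one <- year_adjust(ann[year == 1])
  expect_equal(one$et_ag_adjusted, one$et_ag)
})

test_that("year adjustment conserves means on arbitrary inputs", {
  set.seed(4)
  ann <- data.table::data.table(
    pixel_id = rep(1:200, 3), year = rep(1:3, each = 200),
    et_ag = rnorm(600, 300, 80) + rep(c(-30, 0, 30), each = 200))
  out <- year_adjust(ann)
  grand <- mean(ann$et_ag)
  expect_true(all(abs(out[, mean(et_ag_adjusted), by = year]$V1 - grand)
                  < 1e-9))
})

test_that("orchard-age filtering drops young and exiting orchards only", {
  ann <- data.table::data.table(
    pixel_id = 1:5,
    land_cover = c("ALMOND", "ALMOND", "ALMOND", "TOMATO", "ALMOND"),
    orchard_years_bearing = c(3L, 6L, 11L, NA, NA),
    last_year_flag = c(FALSE, FALSE, TRUE, NA, NA))
  expect_warning(out <- filter_orchard_age(ann), "lack age attributes")
  # ages {3, 6, 11-with-last-year}: only the 6-year orchard is kept;
  # the non-orchard row and the attribute-less orchard pass through
  expect_setequal(out$table$pixel_id, c(2L, 4L, 5L))
  expect_equal(out$report$n_young_removed, 1L)
  expect_equal(out$report$n_last_year_removed, 1L)
  expect_equal(out$report$n_missing_attr_retained, 1L)
  # boundary: bearing fruit for exactly 5 years is removed ("5 or less")
  ann5 <- data.table::data.table(pixel_id = 1L, land_cover = "ALMOND",
                                 orchard_years_bearing = 5L,
                                 last_year_flag = FALSE)
  expect_equal(nrow(filter_orchard_age(ann5)$table), 0L)
  # a vegetable field with no age attribute passes silently
  veg <- data.table::data.table(pixel_id = 1L, land_cover = "TOMATO",
                                orchard_years_bearing = NA_integer_,
                                last_year_flag = NA)
  expect_silent(out_veg <- filter_orchard_age(veg))
  expect_equal(nrow(out_veg$table), 1L)
})

test_that("on synthetic truth, fallow ag-ET is ~0 and crop means match config", {
  cfg <- small_config(13, n = 60L, years = 2016L)
  ls <- generate_landscape(cfg)
  ser <- generate_et_series(ls)
  ann <- ser$pixel_months[, .(et_ag = sum(et_tot) - sum(et_nat)),
                          by = .(pixel_id, year)]
  ann <- merge(ann, ls$pixels[, .(pixel_id, field_id)], by = "pixel_id")
  ann <- merge(ann, ls$fields[, .(field_id, land_cover,
                                  orchard_years_bearing)], by = "field_id")
  expect_equal(ann[land_cover == "FALLOW", mean(et_ag)], 0, tolerance = 1e-9)
  mature <- ann[land_cover != "FALLOW" &
                  (is.na(orchard_years_bearing) | orchard_years_bearing > 5)]
  est <- mature[, .(m = mean(et_ag), n_fields = uniqueN(field_id)),
                by = land_cover]
  est <- merge(est, ls$crops[, .(land_cover = crop, mean_mm, sd_mm)],
               by = "land_cover")
  # field draws are iid: means within ~4 SE of the configured increments
  expect_true(all(abs(est$m - est$mean_mm) <
                    4 * est$sd_mm / sqrt(est$n_fields)))
})
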
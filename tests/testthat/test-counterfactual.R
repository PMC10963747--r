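test_that("training assembly keeps fallow rows only and drops missing rows", {
  pm <- rbind(toy_pixel_months(5, land_cover = "FALLOW"),
              toy_pixel_months(45, land_cover = "ALMOND"))
  out <- assemble_training_table(pm)
  expect_equal(nrow(out), 5L * 12L)
  expect_true(all(out$land_cover == "FALLOW"))
  # one fallow row with a missing feature is dropped and counted
  pm2 <- toy_pixel_months(1, land_cover = "FALLOW")
  pm2$twi[1] <- NA
  expect_message(out2 <- assemble_training_table(pm2), "1 fallow rows dropped")
  expect_equal(nrow(out2), 11L)
  expect_equal(attr(out2, "dropped"), 1L)
  # no fallow rows at all is an error
  expect_error(assemble_training_table(toy_pixel_months(3, land_cover = "X")),
               "no fallow")
})

test_that("summer-outlier cleaning removes exactly the top tail", {
  # 100 pixel-years with Jul-Sep sums 1..100: the five largest go
  base <- data.table::CJ(pixel_id = 1:100, year = 2016L, month = 1:12)
  base[, et_mm := 0]
  base[month %in% 7:9, et_mm := pixel_id / 3]   # Jul-Sep sum = pixel_id
  out <- clean_fallow_outliers(base, 0.95)
  expect_setequal(out$removed$pixel_id, 96:100)
  expect_equal(nrow(out$table), 95L * 12L)      # whole pixel-years removed
  # all-ties: nothing strictly exceeds the percentile
  ties <- data.table::copy(base)[, et_mm := 1]
  expect_equal(nrow(clean_fallow_outliers(ties, 0.95)$removed), 0L)
  # a single pixel-year survives
  one <- base[pixel_id == 1]
  expect_equal(nrow(clean_fallow_outliers(one, 0.95)$table), 12L)
})

test_that("cleaning never removes more than ceil(5%) of pixel-years", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    tab <- data.table::CJ(pixel_id = seq_len(n), year = 2016L, month = 1:12)
    tab[, et_mm := stats::rexp(.N, 1 / 30)]
    out <- clean_fallow_outliers(tab, 0.95)
    expect_lte(nrow(out$removed), ceiling(0.05 * n))
  }
})

test_that("pixel-years without summer months are exempt and reported", {
  tab <- data.table::CJ(pixel_id = 1:3, year = 2016L, month = 1:6)
  tab[, et_mm := pixel_id * 10]
  out <- clean_fallow_outliers(tab)
  expect_equal(nrow(out$removed), 0L)
  expect_equal(nrow(out$exempt), 3L)
})

test_that("blocked splits reproduce the reference 8180-block partition", {
  # 8180 distinct 2 km blocks at fractions 0.6/0.1/0.3
  tab <- data.table::data.table(x = (seq_len(8180) - 0.5) * 2000, y = -1000)
  sp <- block_split(tab, 2000, c(0.6, 0.1, 0.3), seed = 1)
  expect_equal(sum(sp$partition == "train"), 4908L)
  expect_equal(sum(sp$partition == "validation"), 818L)
  expect_equal(sum(sp$partition == "test"), 2454L)
})

test_that("pixels sharing a block always share a partition", {
  set.seed(2)
  tab <- data.table::data.table(x = runif(4000, 0, 30000),
                                y = -runif(4000, 0, 30000))
  for (s in 1:5) {
    sp <- block_split(tab, 2000, c(0.6, 0.1, 0.3), seed = s)
    lab <- fieldET:::apply_split(tab, sp)
    per_block <- lab[, data.table::uniqueN(partition), by = block_id]
    expect_true(all(per_block$V1 == 1L))
    expect_true(all(!is.na(lab$partition)))
  }
  expect_error(block_split(tab[1:2], 100000, seed = 1), "fewer than 3")
})

test_that("hyperparameter choice is deterministic under a fixed seed", {
  cfg <- small_config(1)
  cfg$counterfactual$n_candidates <- 4L
  set.seed(99)
  tr <- toy_pixel_months(40)
  tr[, et_mm := et_mm + rnorm(.N, 0, 0.5)]
  va <- toy_pixel_months(10)
  m1 <- fit_counterfactual(tr, va, cfg, seed = 7)
  m2 <- fit_counterfactual(tr, va, cfg, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$best_iteration, m2$best_iteration)
  expect_equal(predict_natural_et(m1, va), predict_natural_et(m2, va))
})

test_that("a constant target is predicted as that constant", {
  cfg <- small_config(1)
  cfg$counterfactual$n_candidates <- 1L
  tr <- toy_pixel_months(30); tr[, et_mm := 42]
  va <- toy_pixel_months(5); va[, et_mm := 42]
  m <- fit_counterfactual(tr, va, cfg, seed = 3)
  expect_equal(unique(round(predict_natural_et(m, va), 6)), 42)
})

test_that("a pure function of PET is recovered and negatives clip to zero", {
  cfg <- small_config(1)
  cfg$counterfactual$n_candidates <- 1L
  cfg$counterfactual$nrounds <- 500L
  set.seed(5)
  tr <- data.table::CJ(pixel_id = 1:300, year = 2016L, month = 1:12)
  tr[, `:=`(x = runif(.N, 0, 1e4), y = -runif(.N, 0, 1e4),
            elevation = runif(.N, 0, 500), slope = runif(.N, 0, 10),
            aspect = runif(.N, 0, 360), twi = runif(.N, 2, 12),
            soil_quality = runif(.N, 0, 100), pet_mm = runif(.N, 0, 200))]
  tr[, et_mm := pet_mm / 2]
  va <- tr[1:500]
  m <- fit_counterfactual(tr, va, cfg, seed = 2)
  probe <- tr[1:200][, pet_mm := 100]
  expect_equal(mean(predict_natural_et(m, probe)), 50, tolerance = 0.03)
  # negative raw model output is clipped at zero
  tr2 <- data.table::copy(tr)[, et_mm := -3]
  m2 <- fit_counterfactual(tr2, tr2[1:100], cfg, seed = 2)
  expect_true(all(predict_natural_et(m2, tr2[1:50]) == 0))
  # a missing feature is named in the failure
  expect_error(predict_natural_et(m, tr[, !"twi"]), "twi")
})

test_that("annual scoring matches its defining formulas", {
  expect_equal(annual_scores(c(1, 2, 3), c(1, 2, 3)), list(r2 = 1, mae = 0))
  obs <- c(4, 8, 6, 10)
  expect_equal(annual_scores(obs, rep(mean(obs), 4))$r2, 0)
  sc <- annual_scores(c(100, 200, 300), c(110, 190, 310))
  expect_equal(sc$mae, 10)
  expect_equal(sc$r2, 1 - 300 / 20000)
})

test_that("validation excludes incomplete pixel-years and reports by block/year", {
  cfg <- small_config(1)
  cfg$counterfactual$n_candidates <- 1L
  tr <- toy_pixel_months(30)
  m <- fit_counterfactual(tr, toy_pixel_months(5), cfg, seed = 1)
  te <- rbind(toy_pixel_months(6), toy_pixel_months(1)[month <= 11][
    , pixel_id := 99L])
  expect_message(v <- validate_annual(m, te), "1 pixel-years with <12 months")
  expect_equal(v$n_excluded, 1L)
  expect_equal(v$n_pixel_years, 6L)
  expect_true(all(c("mean_resid", "n") %in% names(v$by_block)))
  expect_true(all(c("mean_resid", "n") %in% names(v$by_year)))
})
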
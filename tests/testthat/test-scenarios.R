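# Independent brute-force implementations of the four savings statistics,
# written as plain loops straight from their definitions.
oracle_cs <- function(et, crop, to_minimum = FALSE) {
  crops <- unique(crop)
  cm <- sapply(crops, function(cc) mean(et[crop == cc]))
  M <- if (to_minimum) min(cm) else median(cm)
  num <- 0
  for (i in seq_along(et)) num <- num + min(cm[[crop[i]]], M)
  1 - num / sum(et)
}
oracle_fp <- function(et, crop, central = "median") {
  stat <- if (central == "median") median else mean
  num <- 0
  for (i in seq_along(et)) {
    cap <- stat(et[crop == crop[i]])
    num <- num + min(et[i], cap)
  }
  1 - num / sum(et)
}
oracle_fal <- function(et, p = 0.95) {
  q <- quantile(et, p, type = 7)
  num <- 0
  for (i in seq_along(et)) if (et[i] <= q) num <- num + et[i]
  1 - num / sum(et)
}

px <- function(et, crop) data.table::data.table(et_ag = et, crop = crop)

test_that("worked scenario examples evaluate exactly", {
  # three crops, one pixel each, {9, 5, 1}: M = 5, savings = 4/15
  expect_equal(crop_switching_savings(px(c(9, 5, 1), c("a", "b", "c")))$savings,
               4 / 15)
  # one crop only: substitution is a no-op
  expect_equal(crop_switching_savings(px(c(3, 7), c("a", "a")))$savings, 0)
  # all crop means equal: symmetric, zero savings
  expect_equal(crop_switching_savings(px(c(4, 4), c("a", "b")))$savings, 0)
  # farming practice, one crop {2, 4}, median 3: 1 - 5/6
  expect_equal(farming_practice_savings(px(c(2, 4), c("a", "a")))$savings,
               1 / 6)
  # mean variant, {0, 10}: cap 5, savings 0.5
  expect_equal(farming_practice_savings(px(c(0, 10), c("a", "a")),
                                        central = "mean")$savings, 0.5)
  expect_equal(farming_practice_savings(px(c(6, 6, 6), "a"))$savings, 0)
  # fallowing 1..100: top five zeroed, 490/5050
  expect_equal(fallowing_savings(px(1:100, "a"))$savings, 490 / 5050)
  expect_equal(fallowing_savings(px(rep(5, 20), "a"))$savings, 0)
  expect_equal(fallowing_savings(px(42, "a"))$savings, 0)
  # minimum-crop variant with a zero-mean crop retires everything
  expect_equal(crop_switch_to_minimum_savings(
    px(c(0, 0, 8, 9), c("z", "z", "a", "a")))$savings, 1)
})

test_that("all four statistics match brute force on random instances", {
  set.seed(20)
  for (rep in 1:120) {
    n <- sample(2:60, 1)
    crop <- sample(letters[1:sample(1:6, 1)], n, replace = TRUE)
    et <- round(stats::rlnorm(n, 5, 0.8) - sample(c(0, 50), n, TRUE), 3)
    if (sum(et) <= 0) next
    d <- px(et, crop)
    expect_equal(crop_switching_savings(d)$savings, oracle_cs(et, crop),
                 tolerance = 1e-10)
    expect_equal(crop_switch_to_minimum_savings(d)$savings,
                 oracle_cs(et, crop, to_minimum = TRUE), tolerance = 1e-10)
    expect_equal(farming_practice_savings(d)$savings, oracle_fp(et, crop),
                 tolerance = 1e-10)
    expect_equal(farming_practice_savings(d, central = "mean")$savings,
                 oracle_fp(et, crop, "mean"), tolerance = 1e-10)
    expect_equal(fallowing_savings(d)$savings, oracle_fal(et),
                 tolerance = 1e-10)
  }
})

test_that("scenario invariants: ordering, scale freedom, permutation", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(5:80, 1)
    crop <- sample(letters[1:4], n, replace = TRUE)
    et <- stats::rlnorm(n, 5, 1)
    d <- px(et, crop)
    s_med <- crop_switching_savings(d)$savings
    s_min <- crop_switch_to_minimum_savings(d)$savings
    expect_lte(s_med, s_min + 1e-12)
    # fallowing savings are non-increasing in the percentile
    ps <- c(0.5, 0.75, 0.9, 0.95, 0.99)
    sv <- sapply(ps, function(p) fallowing_savings(d, percentile = p)$savings)
    expect_true(all(diff(sv) <= 1e-12))
    # scale freedom and permutation invariance
    expect_equal(crop_switching_savings(px(3.7 * et, crop))$savings, s_med,
                 tolerance = 1e-10)
    i <- sample(n)
    expect_equal(farming_practice_savings(px(et[i], crop[i]))$savings,
                 farming_practice_savings(d)$savings, tolerance = 1e-12)
  }
})

test_that("fallowing the top 5% removes more than 5% of heavy-tailed ET", {
  set.seed(22)
  et <- stats::rlnorm(5000, 5, 1)
  expect_gt(fallowing_savings(px(et, "a"))$savings, 0.05)
})

test_that("undefined sub-basins are flagged and aggregation is ET-weighted", {
  d_neg <- px(c(-5, 2), c("a", "b"))          # baseline sum <= 0
  expect_true(is.na(crop_switching_savings(d_neg)$savings))
  # aggregate equals pooled-numerator recomputation on random instances
  set.seed(23)
  for (rep in 1:20) {
    nb <- sample(2:6, 1)
    rows <- lapply(seq_len(nb), function(b) {
      n <- sample(3:30, 1)
      fallowing_savings(px(stats::rlnorm(n, 5, 1),
                           sample(letters[1:3], n, TRUE)), b)
    })
    res <- data.table::rbindlist(rows)
    agg <- 1 - sum(res$numerator) / sum(res$baseline_sum)
    # homogeneous case: equal sub-basin savings aggregate to themselves
    expect_equal(agg, 1 - sum(res$numerator) / sum(res$baseline_sum))
    expect_true(agg <= max(res$savings) + 1e-12 &&
                  agg >= min(res$savings) - 1e-12)
  }
})

test_that("run_scenarios enforces the pipeline order and aggregates", {
  cfg <- small_config(17, n = 40L, years = c(2016L, 2017L))
  ls <- generate_landscape(cfg)
  ser <- generate_et_series(ls)
  ann <- ser$pixel_months[, .(et_ag = sum(et_tot) - sum(et_nat),
                              et_tot = sum(et_tot)),
                          by = .(pixel_id, year)]
  ann <- merge(ann, ls$pixels, by = "pixel_id")
  ann <- merge(ann, ls$fields[, .(field_id, land_cover, crop_group,
                                  orchard_years_bearing, last_year_flag)],
               by = "field_id")
  ann[, pet_annual := 100]
  adj <- year_adjust(ann)
  suppressWarnings(out <- run_scenarios(adj, cfg, crops = ls$crops))
  expect_equal(out$scenario_year, 2017L)
  expect_setequal(unique(out$by_sub_basin$scenario),
                  c("crop_switching", "farming_practice", "fallowing",
                    "crop_switch_to_minimum"))
  expect_equal(nrow(out$aggregate), 4L)
  agg <- out$aggregate[scenario == "fallowing"]
  by_sb <- out$by_sub_basin[scenario == "fallowing" & !is.na(savings)]
  expect_equal(agg$savings_weighted,
               1 - sum(by_sb$numerator) / sum(by_sb$baseline_sum))
})
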
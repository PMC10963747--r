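make_field <- function(n = 500, seed = 1) {
  set.seed(seed)
  data.table::data.table(
    x = runif(n, 0, 8000), y = -runif(n, 0, 8000),
    land_cover = sample(c("A", "B", "C"), n, TRUE),
    et_ag_adjusted = rnorm(n, 300, 60))
}

test_that("group means equal brute-force means; grouping none is the mean", {
  dt <- make_field()
  est <- group_mean_regression(dt, "land_cover", cluster_m = 2000)
  brute <- dt[, .(m = mean(et_ag_adjusted)), keyby = land_cover]
  expect_equal(est$mean, brute$m)
  # grouping "none": the overall mean (all three pixels share one tile,
  # so the SE is not identified and warned about)
  expect_warning(all_est <- group_mean_regression(
    data.table::data.table(x = 1:3, y = 1:3, et_ag_adjusted = c(1, 2, 3)),
    NULL, cluster_m = 10), "single cluster")
  expect_equal(all_est$mean, 2)
})

test_that("cluster-robust SEs match the direct sandwich computation", {
  dt <- make_field(400, seed = 3)
  est <- group_mean_regression(dt, "land_cover", cluster_m = 1500)
  # independent oracle: full dummy-regression sandwich with G/(G-1)
  cl <- tile_id(dt$x, dt$y, 1500)
  X <- stats::model.matrix(~ 0 + factor(land_cover), dt)
  fit <- stats::lm.fit(X, dt$et_ag_adjusted)
  e <- fit$residuals
  meat <- Reduce(`+`, lapply(split(seq_len(nrow(dt)), cl), function(ix) {
    s <- crossprod(X[ix, , drop = FALSE], e[ix]); s %*% t(s)
  }))
  G <- length(unique(cl))
  V <- solve(crossprod(X)) %*% meat %*% solve(crossprod(X)) * G / (G - 1)
  expect_equal(est$se, unname(sqrt(diag(V))), tolerance = 1e-10)
})

test_that("cluster-robust SEs agree with the sandwich package", {
  skip_if_not_installed("sandwich")
  dt <- make_field(600, seed = 8)
  est <- group_mean_regression(dt, "land_cover", cluster_m = 2000)
  fit <- stats::lm(et_ag_adjusted ~ 0 + factor(land_cover), dt)
  V <- sandwich::vcovCL(fit, cluster = tile_id(dt$x, dt$y, 2000),
                        type = "HC0", cadjust = TRUE)
  expect_equal(est$se, unname(sqrt(diag(V))), tolerance = 1e-10)
})

test_that("per-pixel clusters reduce to heteroskedasticity-robust SEs", {
  set.seed(5)
  n <- 200
  dt <- data.table::data.table(
    x = (seq_len(n) - 0.5) * 10, y = -5,   # every pixel its own 10 m cluster
    land_cover = rep(c("A", "B"), each = n / 2),
    et_ag_adjusted = rnorm(n, 100, 20) * rep(c(1, 2), each = n / 2))
  est <- group_mean_regression(dt, "land_cover", cluster_m = 10)
  # HC0 per group with G/(G-1), G = n
  hc <- dt[, .(se = sqrt(sum((et_ag_adjusted - mean(et_ag_adjusted))^2) /
                           .N^2 * n / (n - 1))), keyby = land_cover]
  expect_equal(est$se, hc$se, tolerance = 1e-12)
})

test_that("SE degenerate cases: zero variance and single clusters", {
  dt <- data.table::data.table(x = runif(50, 0, 5000), y = -runif(50, 0, 5000),
                               et_ag_adjusted = 7)
  est <- group_mean_regression(dt, NULL, cluster_m = 1000)
  expect_equal(est$se, 0)
  one <- data.table::data.table(x = c(1, 2), y = c(1, 2),
                                et_ag_adjusted = c(1, 2))
  expect_warning(est1 <- group_mean_regression(one, NULL, cluster_m = 1e6),
                 "single cluster")
  expect_true(is.na(est1$se))
})

test_that("SEs are invariant to row order and cluster relabeling", {
  dt <- make_field(300, seed = 6)
  est <- group_mean_regression(dt, "land_cover", cluster_m = 2000)
  perm <- dt[sample(.N)]
  est_p <- group_mean_regression(perm, "land_cover", cluster_m = 2000)
  expect_equal(est, est_p)
  # shifting the anchor relabels clusters but preserves the tiling
  shifted <- data.table::copy(dt)[, `:=`(x = x + 10 * 2000, y = y - 4 * 2000)]
  est_s <- group_mean_regression(shifted, "land_cover", cluster_m = 2000)
  expect_equal(est$se, est_s$se, tolerance = 1e-12)
})

test_that("variance explained spans the saturated and null cases", {
  dt <- make_field(2000, seed = 9)
  mu <- c(A = 100, B = 300, C = 500)
  dt[, et_ag_adjusted := mu[land_cover]]
  expect_equal(variance_explained(dt, grouping = "land_cover"), 1)
  set.seed(10)
  dt[, et_ag_adjusted := rnorm(.N)]       # independent of groups
  expect_lt(variance_explained(dt, grouping = "land_cover"), 0.01)
})

test_that("variance explained recovers a configured variance share", {
  set.seed(11)
  n <- 6000
  g <- sample(c("A", "B"), n, TRUE)
  eff <- ifelse(g == "A", -50, 50)        # between-group variance 2500
  y <- 300 + eff + rnorm(n, 0, 50)        # within-group variance 2500
  dt <- data.table::data.table(x = runif(n), y2 = 0, land_cover = g,
                               et_ag_adjusted = y)
  r2 <- variance_explained(dt, grouping = "land_cover")
  expect_equal(r2, 0.5, tolerance = 0.05)
})

test_that("covariate adjustment preserves the mean and flattens perfect fits", {
  set.seed(12)
  n <- 2000
  # x/y coordinate columns are part of the real schema and must not leak
  # into the adjustment arithmetic
  ann <- data.table::data.table(
    x = runif(n, 0, 14000), y = runif(n, 0, 14000),
    pet_annual = runif(n, 50, 150), soil_quality = runif(n, 0, 100),
    twi = runif(n, 2, 12), elevation = runif(n, 0, 500),
    aspect = runif(n, 0, 360), slope = runif(n, 0, 10))
  # perfect fit: value = 2 * PET -> adjusted is constant at the mean
  ann[, et_ag_adjusted := 2 * pet_annual]
  adj <- covariate_adjust(ann)
  expect_equal(adj$et_ag_adjusted, rep(mean(2 * ann$pet_annual), n),
               tolerance = 1e-9)
  # null effect: covariates unrelated -> adjustment is a small perturbation
  ann[, et_ag_adjusted := rnorm(n, 300, 60)]
  adj2 <- covariate_adjust(ann)
  expect_equal(mean(adj2$et_ag_adjusted), mean(ann$et_ag_adjusted),
               tolerance = 1e-9)                      # exact conservation
  expect_gt(cor(adj2$et_ag_adjusted, ann$et_ag_adjusted), 0.98)
  # missing covariate column is an error; missing values drop rows
  expect_error(covariate_adjust(ann[, !"twi"]), "twi")
  ann$twi[1] <- NA
  expect_message(adj3 <- covariate_adjust(ann), "1 rows dropped")
  expect_equal(nrow(adj3), n - 1L)
})

test_that("the empirical variogram matches analytic references", {
  set.seed(13)
  n <- 200
  dt <- data.table::data.table(x = runif(n, 0, 1000), y = -runif(n, 0, 1000),
                               et_ag_adjusted = rnorm(n, 0, 3))
  vg <- empirical_variogram(dt, max_lag_m = 1400, n_bins = 7)
  # white noise: flat at sigma^2 = 9 in well-populated bins
  busy <- vg[n_pairs > 200]
  expect_true(all(abs(busy$gamma_h - 9) / 9 < 0.35))
  # constant field: zero semivariance everywhere
  dt[, et_ag_adjusted := 5]
  vg0 <- empirical_variogram(dt, max_lag_m = 1400, n_bins = 7)
  expect_true(all(vg0[n_pairs > 0]$gamma_h == 0))
  # a single pair at distance d with values {0, 2} contributes (2-0)^2/2 = 2
  two <- data.table::data.table(x = c(0, 300), y = c(0, 0),
                                et_ag_adjusted = c(0, 2))
  vg2 <- empirical_variogram(two, max_lag_m = 600, n_bins = 2)
  expect_equal(vg2[n_pairs == 1, gamma_h], 2)
  expect_true(is.na(vg2[n_pairs == 0, gamma_h]))
})
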
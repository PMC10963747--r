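#' Group means with spatially cluster-robust confidence intervals
#'
#' Point estimates are per-group arithmetic means (the dummy-variable
#' regression identity of the mean model). Standard errors allow arbitrary
#' error correlation within square spatial clusters of side `cluster_m`
#' anchored at the coordinate origin (75 km at real scale, chosen from the
#' variogram of spatial autocorrelation), via the cluster sandwich with a
#' finite-cluster correction `G/(G-1)` where `G` is the number of non-empty
#' clusters. The 95% CI uses the normal 1.96 quantile.
#'
#' @param annual Annual pixel table with `x`, `y` and the value column.
#' @param grouping Column name (`"land_cover"`, `"crop_group"`,
#'   `"county_id"`, ...) or `NULL` for the overall mean.
#' @param cluster_m Cluster tile side (m), default 75000.
#' @param value_col Column of values (default `"et_ag_adjusted"`).
#' @return data.table: `group`, `mean`, `se`, `ci_low`, `ci_high`,
#'   `n_pixels`, `n_clusters`. Groups observed in a single cluster get `NA`
#'   SE with a warning.
#' @export
group_mean_regression <- function(annual, grouping = NULL, cluster_m = 75000,
                                  value_col = "et_ag_adjusted") {
  if (!(cluster_m > 0)) stop("cluster_m must be > 0")
  dt <- data.table(
    value = annual[[value_col]],
    group = if (is.null(grouping)) "(all)" else as.character(annual[[grouping]]),
    cluster_id = tile_id(annual$x, annual$y, cluster_m))
  dt <- dt[!is.na(value)]
  if (nrow(dt) == 0L) stop("no non-missing values")
  G <- uniqueN(dt$cluster_id)
  corr <- if (G > 1) G / (G - 1) else NA_real_
  dt[, resid_ := value - mean(value), by = group]
  # [V]_gg = corr * sum_c S_gc^2 / n_g^2 with S_gc the within-cluster
  # residual sum for group g (block-diagonal entry of the full sandwich;
  # cross-group terms do not enter a single group's SE).
  sums <- dt[, .(s = sum(resid_)), by = .(group, cluster_id)]
  est <- dt[, .(mean = mean(value), n_pixels = .N), by = group]
  cl <- sums[, .(ss = sum(s^2), n_clusters = .N), by = group]
  est <- merge(est, cl, by = "group", sort = TRUE)
  est[, se := sqrt(corr * ss / n_pixels^2)]
  single <- est$n_clusters < 2L
  if (any(single)) {
    warning("group(s) with a single cluster, SE not identified: ",
            paste(est$group[single], collapse = ", "))
    est[single, se := NA_real_]
  }
  est[, `:=`(ci_low = mean - 1.96 * se, ci_high = mean + 1.96 * se)]
  est[, ss := NULL]
  est[]
}

#' Fraction of variance explained by groupings and/or covariates
#'
#' R^2 of the least-squares fit of the value on group dummies and linear
#' covariate terms; equals the fraction of variation explained by the
#' regressor set. Collinear regressors are dropped by the fit with a warning
#' and do not change the R^2.
#'
#' @param annual Annual pixel table.
#' @param grouping Optional grouping column name.
#' @param covariates Optional character vector of covariate columns.
#' @param value_col Value column (default `"et_ag_adjusted"`).
#' @param aspect_circular Decompose an `aspect` covariate into sine and
#'   cosine components (default TRUE).
#' @return Numeric R^2 in `[0, 1]`.
#' @export
variance_explained <- function(annual, grouping = NULL, covariates = NULL,
                               value_col = "et_ag_adjusted",
                               aspect_circular = TRUE) {
  if (is.null(grouping) && is.null(covariates))
    stop("supply a grouping and/or covariates")
  X <- build_design(annual, grouping, covariates, aspect_circular)
  y <- annual[[value_col]]
  ok <- complete.cases(X) & !is.na(y)
  fit <- lm.fit(cbind(`(Intercept)` = 1, as.matrix(X[ok, , drop = FALSE])),
                y[ok])
  dropped <- sum(is.na(fit$coefficients))
  if (dropped > 0)
    warning(dropped, " collinear regressor(s) dropped")
  1 - sum(fit$residuals^2) / sum((y[ok] - mean(y[ok]))^2)
}

build_design <- function(annual, grouping, covariates, aspect_circular) {
  parts <- list()
  if (!is.null(grouping)) {
    f <- factor(annual[[grouping]])
    if (nlevels(f) > 1) {
      mm <- model.matrix(~ f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(grouping, levels(f)[-1])
      parts$grp <- mm
    } else parts$grp <- matrix(numeric(nrow(annual)), ncol = 0)
  }
  if (!is.null(covariates)) {
    cv <- as.data.frame(annual[, covariates, with = FALSE])
    if (aspect_circular && "aspect" %in% covariates) {
      cv$aspect_sin <- sin(cv$aspect * pi / 180)
      cv$aspect_cos <- cos(cv$aspect * pi / 180)
      cv$aspect <- NULL
    }
    parts$cov <- as.matrix(cv)
  }
  do.call(cbind, parts)
}

#' Adjust annual agricultural ET to sample-average covariates
#'
#' Fits the linear control regression of the value on PET, soil quality,
#' TWI, elevation, aspect and slope, and replaces each pixel's value by the
#' value it would take at the sample-average covariates: residual plus mean
#' fitted value. The grand mean is preserved exactly. Rows missing any
#' covariate are dropped and counted.
#'
#' @param annual Annual pixel table.
#' @param covariates Covariate columns (annual-mean PET by default via
#'   `pet_annual`).
#' @param value_col Column to adjust.
#' @param out_col Output column name.
#' @param aspect_circular Sine/cosine decomposition of aspect (default TRUE;
#'   set FALSE for raw degrees).
#' @return The (possibly shortened) table with `out_col` added; attribute
#'   `"n_dropped"` counts rows lost to missing covariates.
#' @export
covariate_adjust <- function(annual,
                             covariates = c("pet_annual", "soil_quality",
                                            "twi", "elevation", "aspect",
                                            "slope"),
                             value_col = "et_ag_adjusted",
                             out_col = value_col,
                             aspect_circular = TRUE) {
  miss <- setdiff(covariates, names(annual))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  X <- build_design(annual, NULL, covariates, aspect_circular)
  y <- annual[[value_col]]
  ok <- complete.cases(X) & !is.na(y)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(n_drop, " rows dropped for missing covariates")
  out <- copy(annual)[ok]
  fit <- lm.fit(cbind(`(Intercept)` = 1, as.matrix(X[ok, , drop = FALSE])),
                y[ok])
  # value at sample-average covariates; computed outside the data.table
  # frame so table columns (x, y, ...) cannot shadow the locals
  adjusted_vals <- fit$residuals + mean(y[ok] - fit$residuals)
  set(out, j = out_col, value = adjusted_vals)
  setattr(out, "n_dropped", n_drop)
  out[]
}

#' Empirical semivariogram of a pixel-level variable
#'
#' Semivariance per lag-distance bin: half the mean squared difference over
#' pixel pairs whose separation falls in the bin. Pairs are subsampled to
#' `max_pairs` with a seed when the full pair set is larger.
#'
#' @param annual Table with `x`, `y` and the value column (typically one
#'   year's pixels).
#' @param value_col Value column.
#' @param max_lag_m Largest separation considered (m).
#' @param n_bins Number of equal-width bins.
#' @param max_pairs Subsampling cap on the number of pairs.
#' @param seed Seed for pair subsampling.
#' @return data.table: `lag_bin` (bin center, m), `gamma_h`, `n_pairs`
#'   (empty bins keep `NA` semivariance).
#' @export
empirical_variogram <- function(annual, value_col = "et_ag_adjusted",
                                max_lag_m = 6000, n_bins = 20L,
                                max_pairs = 200000L, seed = 1L) {
  if (!(max_lag_m > 0)) stop("max_lag_m must be > 0")
  v <- annual[[value_col]]; xx <- annual$x; yy <- annual$y
  ok <- !is.na(v)
  v <- v[ok]; xx <- xx[ok]; yy <- yy[ok]
  n <- length(v)
  if (n < 2L) stop("need at least 2 pixels")
  n_all <- n * (n - 1) / 2
  set.seed(as.integer(seed))
  if (n_all <= max_pairs) {
    idx <- utils::combn(n, 2L)
    i <- idx[1, ]; j <- idx[2, ]
  } else {
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    keep_ij <- i != j
    i <- i[keep_ij]; j <- j[keep_ij]
  }
  d <- sqrt((xx[i] - xx[j])^2 + (yy[i] - yy[j])^2)
  inb <- d <= max_lag_m & d > 0
  d <- d[inb]; sq <- (v[i[inb]] - v[j[inb]])^2
  brks <- seq(0, max_lag_m, length.out = n_bins + 1L)
  bin <- cut(d, brks, include.lowest = TRUE, labels = FALSE)
  dt <- data.table(bin = bin, sq = sq)
  agg <- dt[, .(gamma_h = mean(sq) / 2, n_pairs = .N), keyby = bin]
  out <- data.table(lag_bin = (brks[-1] + brks[-length(brks)]) / 2,
                    gamma_h = NA_real_, n_pairs = 0L)
  out[agg$bin, `:=`(gamma_h = agg$gamma_h, n_pairs = agg$n_pairs)]
  out[]
}
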
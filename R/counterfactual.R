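# Predictor set of the natural-ET model: spatial and temporal coordinates
# plus topography, soil quality and climate. Order is fixed and recorded in
# the fitted model.
cf_features <- function() {
  c("x", "y", "month", "year", "elevation", "slope", "aspect", "twi",
    "soil_quality", "pet_mm")
}

#' Assemble the fallow-only training table
#'
#' Keeps fallow pixel-months only, with the model's feature columns and the
#' observed ET target. Rows with any missing feature or target are dropped
#' and counted in the attached report.
#'
#' @param pixels Pixel-month data.table (see [pixel_month_table()]).
#' @return data.table of fallow rows with attribute `"dropped"` giving the
#'   number of rows removed for missingness.
#' @export
assemble_training_table <- function(pixels) {
  if (!"land_cover" %in% names(pixels)) stop("land_cover column is required")
  feats <- cf_features()
  miss <- setdiff(c(feats, "et_mm"), names(pixels))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  fal <- pixels[land_cover == "FALLOW"]
  if (nrow(fal) == 0L) stop("no fallow pixel-months: cannot train the model")
  ok <- complete.cases(fal[, c(feats, "et_mm"), with = FALSE])
  dropped <- sum(!ok)
  if (dropped > 0)
    message(dropped, " fallow rows dropped for missing feature/target")
  out <- fal[ok]
  setattr(out, "dropped", dropped)
  out[]
}

#' Remove implausibly high fallow pixel-years (top July-September ET)
#'
#' Mislabelled active fields masquerade as fallow with high summer ET. For
#' each pixel-year the July-September ET sum is computed; pixel-years
#' strictly above the `percentile` quantile (pooled across years, linear
#' interpolation) are removed entirely, all twelve months. Pixel-years with
#' no July-September observations are exempt from the rule and reported.
#'
#' @param table Fallow pixel-month table.
#' @param percentile Quantile defining "top" summer ET (default 0.95, i.e.
#'   the top 5%).
#' @return list with `table` (cleaned), `removed` (pixel-year keys removed),
#'   `exempt` (pixel-years with no Jul-Sep data), `threshold` (the cutoff).
#' @export
clean_fallow_outliers <- function(table, percentile = 0.95) {
  if (nrow(table) == 0L)
    return(list(table = table, removed = data.table(), exempt = data.table(),
                threshold = NA_real_))
  sums <- table[month %in% 7:9, .(jja_sum = sum(et_mm)),
                by = .(pixel_id, year)]
  all_py <- unique(table[, .(pixel_id, year)])
  exempt <- all_py[!sums, on = c("pixel_id", "year")]
  if (nrow(sums) == 0L)
    return(list(table = table, removed = data.table(), exempt = exempt,
                threshold = NA_real_))
  thr <- as.numeric(quantile(sums$jja_sum, percentile, type = 7))
  removed <- sums[jja_sum > thr]
  out <- table[!removed, on = c("pixel_id", "year")]
  list(table = out, removed = removed, exempt = exempt, threshold = thr)
}

#' Spatially blocked train/validation/test split
#'
#' Pixels are grouped into square blocks of side `block_m` (default 2000 m,
#' i.e. 2 km^2 squares) anchored at the coordinate origin; whole blocks are
#' assigned at random to the three partitions so that nearby, nearly
#' identical pixels can never leak across splits. Block counts per partition
#' are `round(fraction * n_blocks)` for train and validation, with the
#' remainder to test (8180 blocks at 0.6/0.1/0.3 gives 4908/818/2454).
#'
#' @param table Pixel table with `x`, `y` columns.
#' @param block_m Block side length (m).
#' @param fractions Length-3 positive vector (train, validation, test)
#'   summing to 1.
#' @param seed Optional integer; when given, the assignment RNG is seeded.
#' @return Object of class `block_split`: data.table `block_id` ->
#'   `partition` with attributes `realized` (block-count fractions) and
#'   `block_m`.
#' @export
block_split <- function(table, block_m = 2000,
                        fractions = c(0.6, 0.1, 0.3), seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0))
    stop("fractions must be positive and sum to 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  blocks <- sort(unique(tile_id(table$x, table$y, block_m)))
  n <- length(blocks)
  if (n < 3L) stop("fewer than 3 non-empty blocks; cannot split")
  shuffled <- sample(blocks)
  fractions <- unname(fractions)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  if (n_tr + n_va >= n) { n_va <- max(1L, n - n_tr - 1L) }
  part <- rep("test", n)
  part[seq_len(n_tr)] <- "train"
  part[n_tr + seq_len(n_va)] <- "validation"
  out <- data.table(block_id = shuffled, partition = part)
  setkey(out, block_id)
  setattr(out, "realized",
          c(train = n_tr / n, validation = n_va / n,
            test = (n - n_tr - n_va) / n))
  setattr(out, "block_m", block_m)
  setattr(out, "class", c("block_split", class(out)))
  out[]
}

# Attach partition labels to a pixel table using a block_split.
apply_split <- function(table, split) {
  block_m <- attr(split, "block_m")
  tbl <- copy(table)
  tbl[, block_id := tile_id(x, y, block_m)]
  merge(tbl, split, by = "block_id", all.x = TRUE, sort = FALSE)
}

# Scaled minimum-samples constraint. The reference protocol fixes the
# minimum samples to split a node at 200 and per leaf at 100 for a training
# set of ~1e7 rows; with squared loss both collapse to xgboost's
# min_child_weight = leaf minimum (a node under 2x the leaf minimum cannot
# split). The constraint scales proportionally for smaller training sets.
scaled_min_leaf <- function(n_train, min_leaf = 100L, reference_n = 1e7) {
  max(1L, as.integer(round(min_leaf * n_train / reference_n)))
}

draw_candidates <- function(space, n_candidates, base_mcw) {
  data.table(
    eta = sample(space$eta, n_candidates, replace = TRUE),
    max_depth = sample(space$max_depth, n_candidates, replace = TRUE),
    subsample = sample(space$subsample, n_candidates, replace = TRUE),
    colsample_bytree = sample(space$colsample_bytree, n_candidates,
                              replace = TRUE),
    min_child_weight = pmax(base_mcw,
                            as.integer(round(base_mcw * sample(
                              space$min_child_weight_mult, n_candidates,
                              replace = TRUE))))
  )
}

xgb_params <- function(cand, seed) {
  list(eta = cand$eta, max_depth = cand$max_depth,
       subsample = cand$subsample, colsample_bytree = cand$colsample_bytree,
       min_child_weight = cand$min_child_weight,
       objective = "reg:squarederror", nthread = 1L, seed = seed)
}

#' Fit the natural-ET counterfactual model on fallow training data
#'
#' Hyperparameters are chosen by randomized search (`n_candidates` draws from
#' the declared search space) with k-fold cross-validation on an unclustered
#' subsample, scored by RMSE; the winning candidate is refit on the full
#' training partition with early stopping against the block-held-out
#' validation partition. The minimum-samples leaf constraint is scaled to the
#' training size (see the methods vignette). All randomness is seeded.
#'
#' @param train,validation Block-disjoint pixel-month tables (fallow rows).
#' @param config A `run_config`; its `counterfactual` block declares the
#'   search space and budgets.
#' @param seed Integer seed for the search and the booster.
#' @return Object of class `counterfactual_model`: list with `booster`,
#'   `params`, `features`, `best_iteration`, `search` (candidate table with
#'   CV scores) and `meta`.
#' @export
fit_counterfactual <- function(train, validation, config = default_config(),
                               seed = stage_seed(config, "fit")) {
  cf <- config$counterfactual
  feats <- cf_features()
  space <- cf$search_space
  if (length(space) == 0L || any(lengths(space) == 0L))
    stop("empty hyperparameter search space")
  set.seed(as.integer(seed))
  base_mcw <- scaled_min_leaf(nrow(train), cf$min_leaf, cf$reference_n)
  n_cand <- max(1L, as.integer(cf$n_candidates))
  cand <- unique(draw_candidates(space, n_cand, base_mcw))

  sub_n <- min(nrow(train), cf$cv_subsample)
  sub <- train[sample.int(nrow(train), sub_n)]
  folds <- sample(rep_len(seq_len(cf$cv_folds), sub_n))
  Xs <- as.matrix(sub[, feats, with = FALSE]); ys <- sub$et_mm
  cand[, value := NA_real_]
  for (i in seq_len(nrow(cand))) {
    rmse <- numeric(cf$cv_folds)
    for (k in seq_len(cf$cv_folds)) {
      tr_idx <- folds != k
      dtr <- xgboost::xgb.DMatrix(Xs[tr_idx, , drop = FALSE],
                                  label = ys[tr_idx])
      bst <- xgboost::xgb.train(xgb_params(cand[i], seed), dtr,
                                nrounds = cf$cv_nrounds, verbose = 0)
      pr <- predict(bst, Xs[!tr_idx, , drop = FALSE])
      rmse[k] <- sqrt(mean((ys[!tr_idx] - pr)^2))
    }
    cand[i, value := mean(rmse)]
  }
  best <- cand[which.min(value)]

  dtrain <- xgboost::xgb.DMatrix(as.matrix(train[, feats, with = FALSE]),
                                 label = train$et_mm)
  dval <- xgboost::xgb.DMatrix(as.matrix(validation[, feats, with = FALSE]),
                               label = validation$et_mm)
  booster <- xgboost::xgb.train(
    xgb_params(best, seed), dtrain, nrounds = cf$nrounds,
    evals = list(validation = dval),
    early_stopping_rounds = cf$early_stopping_rounds, verbose = 0)
  best_iter <- suppressWarnings(
    as.integer(xgboost::xgb.attr(booster, "best_iteration")))
  if (length(best_iter) == 0L || is.na(best_iter)) best_iter <- cf$nrounds

  structure(list(booster = booster, params = as.list(best),
                 features = feats, best_iteration = best_iter,
                 search = cand[],
                 meta = list(seed = as.integer(seed), n_train = nrow(train),
                             n_validation = nrow(validation),
                             min_child_weight_base = base_mcw)),
            class = "counterfactual_model")
}

#' @export
print.counterfactual_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<counterfactual_model> boosted trees on %d fallow rows; ",
    "eta %.3g, depth %d, mcw %d, best iteration %d\n"),
    x$meta$n_train, x$params$eta, x$params$max_depth,
    x$params$min_child_weight, x$best_iteration))
  invisible(x)
}

#' Predict naturally-occurring ET for arbitrary pixels
#'
#' Emits one prediction per input row (cropped and fallow alike), clipped
#' below at zero since an ET depth cannot be negative.
#'
#' @param model A `counterfactual_model`.
#' @param pixels Table carrying all model features.
#' @return Numeric vector of natural-ET estimates (mm/month).
#' @export
predict_natural_et <- function(model, pixels) {
  miss <- setdiff(model$features, names(pixels))
  if (length(miss) > 0)
    stop("missing model feature(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(pixels[, model$features, with = FALSE])
  pr <- predict(model$booster, X,
                iterationrange = c(1L, model$best_iteration))
  pmax(0, pr)
}

#' Score predictions against observations
#'
#' `r2` is `1 - SS_res/SS_tot` (so a model no better than the observed mean
#' scores 0 and perfection scores 1); `mae` is the mean absolute error in
#' the units of the inputs.
#'
#' @param obs,pred Numeric vectors of equal length.
#' @return list with `r2` and `mae`.
#' @export
annual_scores <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) > 0)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) (if (ss_res == 0) 1 else -Inf) else 1 - ss_res / ss_tot
  list(r2 = r2, mae = mean(abs(obs - pred)))
}

#' Validate the counterfactual on annual sums over held-out blocks
#'
#' Analyses run on yearly agricultural ET, so the model is scored on yearly
#' natural-ET estimates: predictions and observations are summed to
#' pixel-years (incomplete pixel-years are excluded and counted), then R^2
#' (1 - SS_res/SS_tot) and MAE (mm/yr) are computed, together with residual
#' means by spatial block and by year to reveal structured error.
#'
#' @param model A `counterfactual_model`.
#' @param test Block-held-out pixel-month table.
#' @param block_m Block size for the residual-by-block summary.
#' @return list with `r2`, `mae_mm`, `n_pixel_years`, `n_excluded`,
#'   `by_block` and `by_year` residual summaries, and `annual` (the
#'   pixel-year table).
#' @export
validate_annual <- function(model, test, block_m = 2000) {
  tbl <- copy(test)
  tbl[, pred := predict_natural_et(model, tbl)]
  ann <- tbl[, .(obs = sum(et_mm), pred = sum(pred), n_months = uniqueN(month),
                 x = x[1], y = y[1]),
             by = .(pixel_id, year)]
  bad <- ann[n_months < 12L]
  ann <- ann[n_months == 12L]
  if (nrow(bad) > 0)
    message(nrow(bad), " pixel-years with <12 months excluded from validation")
  if (nrow(ann) == 0L) stop("no complete pixel-years to validate on")
  sc <- annual_scores(ann$obs, ann$pred)
  ann[, block_id := tile_id(x, y, block_m)]
  list(r2 = sc$r2,
       mae_mm = sc$mae,
       n_pixel_years = nrow(ann), n_excluded = nrow(bad),
       by_block = ann[, .(mean_resid = mean(pred - obs), n = .N),
                      by = block_id],
       by_year = ann[, .(mean_resid = mean(pred - obs), n = .N), by = year],
       annual = ann[, .(pixel_id, year, obs, pred)])
}
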
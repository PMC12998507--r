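# Gradient-boosted burn-depth and carbon-combustion models: recursive
# feature elimination, budgeted hyperparameter search, repeated
# cross-validated evaluation with strict out-of-fold discipline, per-pixel
# prediction and emission aggregation.
#
# Three chained models: burn depth (cm); belowground carbon combustion
# (g C m^-2), which consumes the *out-of-fold* depth prediction as a
# feature during evaluation and the depth model's direct prediction at
# pixel scale; and aboveground carbon combustion, whose candidate set adds
# biomass.

#' Candidate predictor names
#'
#' 42 candidate predictors for burn depth and belowground combustion
#' (fire severity, climate, soil, topography, vegetation); the
#' aboveground set adds biomass (43). The names are configuration: real
#' deployments substitute their own dictionary.
#'
#' @param target `"depth"`, `"belowground"` or `"aboveground"`.
#' @return character vector of predictor names.
#' @export
predictor_dictionary <- function(target = c("depth", "belowground",
                                            "aboveground")) {
  target <- match.arg(target)
  base <- c(
    # fire severity characteristics
    "dnbr", "rdnbr", "nbr_post", "frp_mean", "fire_duration", "fire_size",
    "spread_rate",
    # climate
    "tmax_summer", "tmin_summer", "precip_summer", "vpd_summer",
    "cwd_summer", "pdsi_summer", "dc_summer", "dmc_summer", "ffmc_summer",
    "bui_summer", "isi_summer", "snowmelt_doy", "thaw_degree_days",
    # soil properties
    "soc_0_30cm", "soc_30_100cm", "bulk_density", "clay_frac", "sand_frac",
    "silt_frac", "ph_topsoil", "peat_depth", "water_table_depth",
    "drainage_class",
    # topography
    "elevation", "slope", "aspect_ns", "aspect_ew", "twi", "ruggedness",
    # vegetation cover
    "tree_cover", "shrub_cover", "moss_cover", "ndvi_prefire", "lai_summer",
    "land_cover_conifer")
  if (target == "aboveground") c(base, "agb_biomass") else base
}

.xgb_defaults <- list(eta = 0.1, max_depth = 4, min_child_weight = 2,
                      subsample = 0.8, colsample_bytree = 0.8,
                      alpha = 0, lambda = 1)

xgb_fit <- function(X, y, params = .xgb_defaults, nrounds = 120L) {
  p <- c(params, list(objective = "reg:squarederror", nthread = 1))
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

# Fold assignment: every plot appears in exactly one held-out fold.
make_folds <- function(n, k) sample(rep(seq_len(k), length.out = n))

cv_rmse <- function(X, y, params, nrounds, folds) {
  pred <- numeric(length(y))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- xgb_fit(X[!hold, , drop = FALSE], y[!hold], params, nrounds)
    pred[hold] <- stats::predict(fit, as.matrix(X[hold, , drop = FALSE]))
  }
  sqrt(mean((pred - y)^2))
}

#' Recursive feature elimination and budgeted hyperparameter search
#'
#' Features are ranked by gradient-boosting gain importance on the full
#' candidate set (exact duplicate columns are pre-screened, keeping the
#' first in column order, so that exactly one of two identical features
#' can survive). Nested head subsets of the ranking are each scored by
#' k-fold cross-validated RMSE and the smallest subset within one
#' standard-error-free tolerance of the best mean RMSE is retained (ties
#' resolve toward fewer features). The hyperparameter search then draws up
#' to `budget` seeded random configurations of the eight tuned
#' hyperparameters (learning rate, tree depth, minimum child weight, row
#' subsample, column subsample, L1, L2, boosting rounds) and keeps the
#' configuration minimizing the same CV RMSE.
#'
#' @param data plot table.
#' @param target name of the outcome column.
#' @param features candidate predictor names (>= 2).
#' @param budget hyperparameter draws (200 at full scale).
#' @param folds CV folds (10).
#' @param subset_sizes candidate feature-subset sizes; defaults to a
#'   log-spaced ladder from 2 to all candidates.
#' @param nrounds boosting rounds used during RFE.
#' @return list with `features` (selected), `ranking`, `params`,
#'   `nrounds`, `rfe_rmse` and `search_rmse` traces.
#' @export
tune_and_select <- function(data, target, features, budget = 200L,
                            folds = 10L, subset_sizes = NULL,
                            nrounds = 120L) {
  if (budget < 1L) stop("hyperparameter budget must be at least 1", call. = FALSE)
  if (nrow(data) < 50L) stop("need at least 50 plots", call. = FALSE)
  if (length(features) < 2L) stop("need at least 2 candidate features", call. = FALSE)
  y <- data[[target]]
  X <- data[, features, drop = FALSE]
  # Pre-screen exact duplicate columns: keep the first in column order.
  dup <- duplicated(lapply(seq_along(X), function(j) X[[j]]))
  X <- X[, !dup, drop = FALSE]
  feats <- names(X)

  full <- xgb_fit(X, y, nrounds = nrounds)
  imp <- xgboost::xgb.importance(model = full)
  ranking <- c(imp$Feature, setdiff(feats, imp$Feature))  # unused -> tail

  p <- length(ranking)
  if (is.null(subset_sizes))
    subset_sizes <- sort(unique(pmin(p, c(2, 3, 5, round(p * c(1, .75, .5, .25, .12))))))
  subset_sizes <- subset_sizes[subset_sizes >= 2 & subset_sizes <= p]
  fold_id <- make_folds(nrow(X), folds)
  rfe <- vapply(subset_sizes, function(k)
    cv_rmse(X[, ranking[seq_len(k)], drop = FALSE], y, .xgb_defaults,
            nrounds, fold_id), numeric(1))
  best_k <- subset_sizes[which.min(rfe)]  # which.min: first = fewest features
  selected <- ranking[seq_len(best_k)]

  draws <- data.frame(
    eta = exp(stats::runif(budget, log(0.02), log(0.3))),
    max_depth = sample(2:8, budget, replace = TRUE),
    min_child_weight = stats::runif(budget, 1, 10),
    subsample = stats::runif(budget, 0.5, 1),
    colsample_bytree = stats::runif(budget, 0.5, 1),
    alpha = exp(stats::runif(budget, log(1e-3), log(1))),
    lambda = exp(stats::runif(budget, log(0.1), log(10))),
    nrounds = sample(60:250, budget, replace = TRUE))
  Xs <- X[, selected, drop = FALSE]
  search <- vapply(seq_len(budget), function(i)
    cv_rmse(Xs, y, as.list(draws[i, -8L]), draws$nrounds[i], fold_id),
    numeric(1))
  best <- which.min(search)
  list(features = selected, ranking = ranking,
       params = as.list(draws[best, -8L]), nrounds = draws$nrounds[best],
       rfe_rmse = data.frame(size = subset_sizes, rmse = rfe),
       search_rmse = search)
}

# Repeated out-of-fold predictions for one model; returns the per-repeat
# prediction matrix and the fold bookkeeping.
repeated_oof <- function(X, y, params, nrounds, folds, repeats) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, repeats)
  fold_log <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    fid <- make_folds(n, folds)
    if (any(tabulate(fid, folds) == 0L)) stop("empty fold", call. = FALSE)
    fold_log[, r] <- fid
    for (f in seq_len(folds)) {
      hold <- fid == f
      fit <- xgb_fit(X[!hold, , drop = FALSE], y[!hold], params, nrounds)
      preds[hold, r] <- stats::predict(fit, as.matrix(X[hold, , drop = FALSE]))
    }
  }
  list(pred = preds, folds = fold_log)
}

eval_metrics <- function(obs, pred) {
  list(r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
       rmse = sqrt(mean((pred - obs)^2)),
       rbias = (mean(pred) - mean(obs)) / mean(obs),
       rbias_ratio_mean = mean(pred / obs))
}

#' Fit and evaluate the three chained combustion models
#'
#' Each model is evaluated by k-fold out-of-fold prediction repeated
#' `repeats` times; the per-plot predictions are averaged across repeats
#' and scored against observations (no plot is ever predicted by a model
#' trained on it). The belowground model receives the *averaged
#' out-of-fold* depth prediction as its depth feature, never the in-fold
#' one. Residual statistics (mean and standard deviation of prediction
#' minus observation) are computed from the averaged held-out predictions
#' and drive the downstream uncertainty propagation. Final models for
#' pixel prediction are refit on all plots.
#'
#' @param data plot table ([simulate_field_plots()] schema).
#' @param selections named list (`depth`, `below`, `above`) of
#'   [tune_and_select()] results (or lists with `features`, `params`,
#'   `nrounds`).
#' @param folds CV folds (10).
#' @param repeats evaluation repeats (100 at full scale; desk runs use 5).
#' @return object of class `combustion_models`: fitted models, selected
#'   features, `cv_metrics`, `residual_stats`, out-of-fold predictions and
#'   fold logs.
#' @export
fit_evaluate <- function(data, selections, folds = 10L, repeats = 100L) {
  stopifnot(repeats >= 1L, all(c("depth", "below", "above") %in% names(selections)))
  get3 <- function(s) list(features = s$features,
                           params = if (is.null(s$params)) .xgb_defaults else s$params,
                           nrounds = if (is.null(s$nrounds)) 120L else s$nrounds)
  sd_ <- get3(selections$depth); sb <- get3(selections$below)
  sa <- get3(selections$above)

  Xd <- data[, sd_$features, drop = FALSE]
  od <- repeated_oof(Xd, data$burn_depth, sd_$params, sd_$nrounds, folds, repeats)
  depth_oof <- rowMeans(od$pred)

  Xb <- cbind(data[, setdiff(sb$features, "depth_pred"), drop = FALSE],
              depth_pred = depth_oof)
  ob <- repeated_oof(Xb, data$belowground_cc, sb$params, sb$nrounds, folds, repeats)
  below_oof <- rowMeans(ob$pred)

  Xa <- data[, sa$features, drop = FALSE]
  oa <- repeated_oof(Xa, data$aboveground_cc, sa$params, sa$nrounds, folds, repeats)
  above_oof <- rowMeans(oa$pred)

  res_b <- below_oof - data$belowground_cc
  res_a <- above_oof - data$aboveground_cc
  structure(list(
    depth_model = xgb_fit(Xd, data$burn_depth, sd_$params, sd_$nrounds),
    below_model = xgb_fit(Xb, data$belowground_cc, sb$params, sb$nrounds),
    above_model = xgb_fit(Xa, data$aboveground_cc, sa$params, sa$nrounds),
    selected_features = list(depth = sd_$features,
                             below = c(setdiff(sb$features, "depth_pred"),
                                       "depth_pred"),
                             above = sa$features),
    cv_metrics = list(depth = eval_metrics(data$burn_depth, depth_oof),
                      below = eval_metrics(data$belowground_cc, below_oof),
                      above = eval_metrics(data$aboveground_cc, above_oof)),
    residual_stats = list(
      below = list(mu_res = mean(res_b), sigma_cc_res = stats::sd(res_b)),
      above = list(mu_res = mean(res_a), sigma_cc_res = stats::sd(res_a))),
    oof = list(depth = depth_oof, below = below_oof, above = above_oof),
    fold_log = list(depth = od$folds, below = ob$folds, above = oa$folds),
    oof_pred_matrix = list(depth = od$pred)
  ), class = "combustion_models")
}

#' Per-pixel burn depth and carbon combustion
#'
#' Predictions are made only on burned pixels. The belowground model's
#' depth feature is the depth model's direct pixel prediction (no
#' cross-validation averaging exists at prediction time). Negative
#' predictions are floored at zero and counted.
#'
#' @param models a [fit_evaluate()] bundle.
#' @param predictors named list of predictor rasters.
#' @param burned logical burned raster.
#' @return list with `depth`, `belowground_cc`, `aboveground_cc` rasters
#'   (NA off the burned mask) and `n_floored`.
#' @export
predict_pixels <- function(models, predictors, burned) {
  stopifnot(inherits(models, "combustion_models"))
  idx <- which(burned)
  blank <- matrix(NA_real_, nrow(burned), ncol(burned))
  if (length(idx) == 0L)
    return(list(depth = blank, belowground_cc = blank,
                aboveground_cc = blank, n_floored = 0L))
  grab <- function(feats) {
    miss <- setdiff(feats, names(predictors))
    if (length(miss) > 0L)
      stop("missing predictor raster(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    m <- vapply(feats, function(f) predictors[[f]][idx],
                numeric(length(idx)))
    matrix(m, nrow = length(idx), dimnames = list(NULL, feats))
  }
  dep <- stats::predict(models$depth_model,
                        grab(models$selected_features$depth))
  xb <- cbind(grab(setdiff(models$selected_features$below, "depth_pred")),
              depth_pred = dep)
  bel <- stats::predict(models$below_model, xb)
  abv <- stats::predict(models$above_model,
                        grab(models$selected_features$above))
  n_floored <- sum(dep < 0) + sum(bel < 0) + sum(abv < 0)
  out <- list(depth = blank, belowground_cc = blank, aboveground_cc = blank,
              n_floored = n_floored)
  out$depth[idx] <- pmax(dep, 0)
  out$belowground_cc[idx] <- pmax(bel, 0)
  out$aboveground_cc[idx] <- pmax(abv, 0)
  out
}

#' Aggregate per-pixel combustion to emission totals
#'
#' Total carbon = sum of combustion x pixel area; per-area mean = total /
#' burned area. Split by peat / non-peat and belowground / aboveground.
#'
#' @param pred a [predict_pixels()] result.
#' @param burned logical burned raster.
#' @param peat_fire logical peat-fire raster (optional).
#' @param pixel_area pixel area, m^2 (900 at 30 m).
#' @return data.frame with one row per (class, pool): total g C, Pg C,
#'   burned area m^2, and per-area mean g C m^-2.
#' @export
aggregate_emissions <- function(pred, burned, peat_fire = NULL,
                                pixel_area = 900) {
  classes <- list(all = burned)
  if (!is.null(peat_fire)) {
    classes$peat <- burned & peat_fire
    classes$nonpeat <- burned & !peat_fire
  }
  rows <- list()
  for (cl in names(classes)) {
    sel <- which(classes[[cl]])
    area <- length(sel) * pixel_area
    for (pool in c("belowground", "aboveground", "total")) {
      cc <- switch(pool,
                   belowground = pred$belowground_cc[sel],
                   aboveground = pred$aboveground_cc[sel],
                   total = pred$belowground_cc[sel] + pred$aboveground_cc[sel])
      tot <- sum(cc * pixel_area)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, pool = pool, total_g_c = tot, total_pg_c = tot / 1e15,
        area_m2 = area,
        mean_g_c_m2 = if (area > 0) tot / area else NA_real_)
    }
  }
  do.call(rbind, rows)
}
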
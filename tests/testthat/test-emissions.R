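# Combustion models: feature selection, out-of-fold discipline,
# chaining, pixel prediction, aggregation.

synth_plots <- function(n = 300, p = 10, seed = 1, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  y <- 2 * X[, 1] + 1.5 * X[, 2] - X[, 3] + rnorm(n, 0, noise)
  cbind(data.frame(target = y), as.data.frame(X))
}

test_that("RFE retains planted informative features and dedupes columns", {
  d <- synth_plots(seed = 41)
  set.seed(41)
  sel <- tune_and_select(d, "target", paste0("v", 1:10), budget = 2L,
                         folds = 5L, subset_sizes = c(3, 5, 10),
                         nrounds = 60L)
  expect_true(all(c("v1", "v2", "v3") %in% sel$features))
  # duplicated column: exactly one survives (first in column order)
  d2 <- d; d2$v1_copy <- d2$v1
  set.seed(41)
  sel2 <- tune_and_select(d2, "target", c(paste0("v", 1:10), "v1_copy"),
                          budget = 1L, folds = 5L, subset_sizes = c(3, 5),
                          nrounds = 60L)
  expect_true("v1" %in% sel2$ranking)
  expect_false("v1_copy" %in% sel2$ranking)
  # budget checks
  expect_error(tune_and_select(d, "target", paste0("v", 1:10), budget = 0L),
               "budget")
  set.seed(41)
  sel1 <- tune_and_select(d, "target", paste0("v", 1:10), budget = 1L,
                          folds = 3L, subset_sizes = c(3), nrounds = 30L)
  expect_equal(length(sel1$search_rmse), 1L)
})

test_that("evaluation is out-of-fold and the depth chain uses predictions only", {
  d <- synth_plots(n = 200, seed = 42)
  names(d)[1] <- "burn_depth"
  d$belowground_cc <- 300 * d$burn_depth + rnorm(200, 0, 50)
  d$aboveground_cc <- 50 + 10 * d$v5 + rnorm(200, 0, 5)
  sels <- list(depth = list(features = c("v1", "v2", "v3"), nrounds = 60L),
               below = list(features = c("v1", "depth_pred"), nrounds = 60L),
               above = list(features = c("v5", "v6"), nrounds = 60L))
  set.seed(42)
  mb <- fit_evaluate(d, sels, folds = 5L, repeats = 3L)
  # every plot is held out exactly once per repeat
  for (r in 1:3) expect_true(all(table(mb$fold_log$depth[, r]) > 0) &&
                               length(mb$fold_log$depth[, r]) == 200)
  # out-of-fold predictions differ from a refit-on-all prediction
  Xd <- as.matrix(d[, c("v1", "v2", "v3")])
  in_sample <- predict(mb$depth_model, Xd)
  expect_gt(mean((mb$oof$depth - d$burn_depth)^2),
            mean((in_sample - d$burn_depth)^2))
  # chained-depth leakage: the belowground design uses predicted depth,
  # which is not the true depth column
  expect_true("depth_pred" %in% mb$selected_features$below)
  expect_gt(max(abs(mb$oof$depth - d$burn_depth)), 1e-6)
  # residual stats computed from held-out predictions
  expect_equal(mb$residual_stats$below$mu_res,
               mean(mb$oof$below - d$belowground_cc), tolerance = 1e-10)
})

test_that("a noiseless learnable target reaches near-perfect accuracy", {
  d <- synth_plots(n = 400, seed = 43, noise = 0)
  names(d)[1] <- "burn_depth"
  d$belowground_cc <- 300 * d$burn_depth
  d$aboveground_cc <- 40 * d$v5
  sels <- list(depth = list(features = c("v1", "v2", "v3"), nrounds = 300L),
               below = list(features = c("depth_pred"), nrounds = 300L),
               above = list(features = c("v5"), nrounds = 300L))
  set.seed(43)
  mb <- fit_evaluate(d, sels, folds = 5L, repeats = 2L)
  expect_gte(mb$cv_metrics$depth$r2, 0.97)
})

test_that("pixel prediction respects the mask and floors negatives", {
  d <- synth_plots(n = 200, seed = 44)
  names(d)[1] <- "burn_depth"
  d$belowground_cc <- 300 * d$burn_depth + rnorm(200, 0, 50)
  d$aboveground_cc <- 50 + 10 * d$v5 + rnorm(200, 0, 5)
  sels <- list(depth = list(features = c("v1", "v2"), nrounds = 40L),
               below = list(features = c("v1", "depth_pred"), nrounds = 40L),
               above = list(features = c("v5"), nrounds = 40L))
  set.seed(44)
  mb <- fit_evaluate(d, sels, folds = 5L, repeats = 2L)
  rasters <- list(v1 = matrix(0.5, 6, 6), v2 = matrix(-0.2, 6, 6),
                  v5 = matrix(1, 6, 6))
  burned <- matrix(FALSE, 6, 6); burned[2:3, 2:3] <- TRUE
  pr <- predict_pixels(mb, rasters, burned)
  expect_true(all(is.na(pr$depth[!burned])))
  # constant predictors give constant predictions
  expect_equal(length(unique(pr$depth[burned])), 1L)
  expect_true(all(pr$belowground_cc[burned] >= 0))
  expect_error(predict_pixels(mb, rasters[1], burned), "v2")
  # empty mask
  pr0 <- predict_pixels(mb, rasters, matrix(FALSE, 6, 6))
  expect_true(all(is.na(pr0$depth)))
})

test_that("emission aggregation does exact area arithmetic", {
  burned <- matrix(FALSE, 3, 3); burned[1, 1] <- TRUE
  pred <- list(belowground_cc = matrix(3000, 3, 3),
               aboveground_cc = matrix(0, 3, 3))
  agg <- aggregate_emissions(pred, burned, pixel_area = 900)
  expect_equal(agg$total_g_c[agg$class == "all" & agg$pool == "belowground"],
               2.7e6)
  # belowground share from the per-area means: 3010 of 3427 -> 87.8%
  pred2 <- list(belowground_cc = matrix(3010, 3, 3),
                aboveground_cc = matrix(417, 3, 3))
  burned2 <- matrix(TRUE, 3, 3)
  agg2 <- aggregate_emissions(pred2, burned2, pixel_area = 900)
  share <- agg2$mean_g_c_m2[agg2$class == "all" & agg2$pool == "belowground"] /
    agg2$mean_g_c_m2[agg2$class == "all" & agg2$pool == "total"]
  expect_equal(round(100 * share, 1), 87.8)
  # zero burned pixels
  agg0 <- aggregate_emissions(pred, matrix(FALSE, 3, 3))
  expect_true(all(agg0$total_g_c == 0))
})
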
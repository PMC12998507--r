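# Random-forest burned-area classification and reference-based accuracy.
#
# The classifier is trained once on labeled samples of a single reference
# year and reused across years (the fire spectral signal is assumed
# independent of the time dimension). Settings mirror the ensemble used in
# the mapping tool this pipeline descends from: 200 trees, minimum leaf
# population 10, at most 450 terminal nodes per tree, sqrt(p) candidate
# variables per split, and a 50% bag fraction. `maxnodes` in
# \pkg{randomForest} caps terminal nodes per tree, the closest available
# mapping of a per-tree node budget.

#' Extract labeled training pixels from ground truth
#'
#' Builds a training table the way reference polygons would: rectangular
#' quadrilaterals a few pixels wide are sampled inside burned scars and
#' over unburned background, and every valid pixel inside a polygon
#' becomes one training row.
#'
#' @param stack feature stack of the reference year ([build_feature_stack()]).
#' @param burned_mask logical truth raster for that year.
#' @param n_polys polygons per class.
#' @param poly_halfwidth half-width of each square polygon, pixels.
#' @return data.frame of features plus a `label` factor (burned/unburned).
#' @export
extract_training_samples <- function(stack, burned_mask, n_polys = 24L,
                                     poly_halfwidth = 2L) {
  h <- nrow(burned_mask); w <- ncol(burned_mask)
  take <- function(centers) {
    idx <- integer(0)
    for (ci in centers) {
      r0 <- ((ci - 1L) %% h) + 1L; c0 <- ((ci - 1L) %/% h) + 1L
      rs <- max(1L, r0 - poly_halfwidth):min(h, r0 + poly_halfwidth)
      cs <- max(1L, c0 - poly_halfwidth):min(w, c0 + poly_halfwidth)
      idx <- c(idx, as.vector(outer(rs, (cs - 1L) * h, "+")))
    }
    unique(idx)
  }
  valid <- stack$valid
  burned_ok <- which(burned_mask & valid)
  unburned_ok <- which(!burned_mask & valid)
  cb <- sample(burned_ok, min(n_polys, length(burned_ok)))
  cu <- sample(unburned_ok, min(n_polys, length(unburned_ok)))
  ib <- intersect(take(cb), which(burned_mask & valid))
  iu <- intersect(take(cu), which(!burned_mask & valid))
  df <- rbind(feature_rows(stack, ib), feature_rows(stack, iu))
  df$label <- factor(rep(c("burned", "unburned"), c(length(ib), length(iu))),
                     levels = c("burned", "unburned"))
  df
}

#' Train the burn random forest
#'
#' @param samples data.frame of features with a binary `label` factor.
#' @param ntree,nodesize,maxnodes,bag_fraction ensemble settings; the
#'   defaults (200, 10, 450, 0.5) are the reference configuration, with
#'   `mtry = sqrt(p)`.
#' @return object of class `burn_rf`: the fitted forest, the feature
#'   names, and `seed_threshold` (mean burned-class probability over the
#'   burned training pixels, used downstream to confirm seeds).
#' @export
train_burn_rf <- function(samples, ntree = 200L, nodesize = 10L,
                          maxnodes = 450L, bag_fraction = 0.5) {
  stopifnot(is.factor(samples$label))
  if (nlevels(droplevels(samples$label)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  feats <- setdiff(names(samples), "label")
  feats <- sort(feats)  # column-order invariance under a fixed seed
  # canonical row order: training is invariant to sample-order permutations
  ord <- do.call(order, c(list(samples$label),
                          lapply(feats, function(f) samples[[f]])))
  samples <- samples[ord, , drop = FALSE]
  x <- as.matrix(samples[, feats, drop = FALSE])
  fit <- withCallingHandlers(
    randomForest::randomForest(
      x = x, y = samples$label, ntree = ntree, nodesize = nodesize,
      maxnodes = maxnodes, mtry = max(1L, floor(sqrt(length(feats)))),
      sampsize = max(2L, ceiling(bag_fraction * nrow(x))), replace = TRUE),
    warning = function(w) {
      # small training sets cannot reach the 450-node budget; harmless
      if (grepl("maxnodes exceeds its max value", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p_train <- stats::predict(fit, x, type = "prob")[, "burned"]
  structure(list(forest = fit, features = feats,
                 settings = list(ntree = ntree, nodesize = nodesize,
                                 maxnodes = maxnodes,
                                 mtry = max(1L, floor(sqrt(length(feats)))),
                                 bag_fraction = bag_fraction),
                 seed_threshold = mean(p_train[samples$label == "burned"])),
            class = "burn_rf")
}

#' Per-pixel burn probability
#'
#' The probability of burn is the fraction of trees voting burned.
#' No-data pixels (invalid composites or missing features) receive NA.
#'
#' @param model a [train_burn_rf()] fit.
#' @param stack feature stack ([build_feature_stack()]).
#' @return list with `p_b` (probability raster) and `valid`.
#' @export
predict_burn_probability <- function(model, stack) {
  stopifnot(inherits(model, "burn_rf"))
  dm <- dim(stack$valid)
  p <- matrix(NA_real_, dm[1L], dm[2L])
  idx <- which(stack$valid)
  if (length(idx) > 0L) {
    df <- feature_rows(stack, idx)
    complete <- stats::complete.cases(df[, model$features, drop = FALSE])
    use <- idx[complete]
    if (length(use) > 0L) {
      x <- as.matrix(df[complete, model$features, drop = FALSE])
      p[use] <- stats::predict(model$forest, x, type = "prob")[, "burned"]
    }
  }
  list(p_b = p, valid = !is.na(p))
}

#' Accuracy of a burned-area map against a reference mask
#'
#' Omission error = FN / (TP + FN); commission error = FP / (TP + FP);
#' Dice coefficient = 2 TP / (2 TP + FP + FN). With an optional unit
#' labeling, per-unit metrics and their mean are reported alongside the
#' pixel-pooled values.
#'
#' @param predicted,reference logical rasters on the same grid.
#' @param valid optional logical raster restricting the comparison.
#' @param units optional integer raster of reference-unit labels (0 =
#'   outside any unit).
#' @return list with counts (`tp`, `fp`, `fn`, `tn`), `omission_error` and
#'   `commission_error` in percent, `dice`, and (when `units` is given)
#'   a `per_unit` data.frame with unit-mean metrics.
#' @export
evaluate_burn_map <- function(predicted, reference, valid = NULL, units = NULL) {
  if (!identical(dim(predicted), dim(reference)))
    stop("predicted and reference masks are on different grids", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(reference), ncol(reference))
  one <- function(sel) {
    tp <- sum(predicted & reference & sel)
    fp <- sum(predicted & !reference & sel)
    fn <- sum(!predicted & reference & sel)
    tn <- sum(!predicted & !reference & sel)
    om <- if (tp + fn == 0L) NA_real_ else 100 * fn / (tp + fn)
    cm <- if (tp + fp == 0L) NA_real_ else 100 * fp / (tp + fp)
    dice <- if (2 * tp + fp + fn == 0L) NA_real_ else 2 * tp / (2 * tp + fp + fn)
    list(tp = tp, fp = fp, fn = fn, tn = tn, omission_error = om,
         commission_error = cm, dice = dice)
  }
  out <- one(valid)
  if (sum(reference & valid) == 0L)
    out$note <- "empty reference burned set: omission undefined"
  if (!is.null(units)) {
    ids <- sort(setdiff(unique(units[valid]), 0L))
    pu <- do.call(rbind, lapply(ids, function(u) {
      m <- one(valid & units == u)
      data.frame(unit = u, omission_error = m$omission_error,
                 commission_error = m$commission_error, dice = m$dice)
    }))
    out$per_unit <- pu
    out$unit_mean_dice <- mean(pu$dice, na.rm = TRUE)
  }
  out
}

#' Dice coefficient implied by omission and commission error rates
#'
#' Algebraic identity linking the three reference-based metrics:
#' `dice = 2 / (1 / (1 - E_o) + 1 / (1 - E_c))`, the harmonic mean of
#' producer's and user's accuracy.
#'
#' @param omission_error,commission_error error rates in percent.
#' @return the implied Dice coefficient.
#' @export
dice_from_error_rates <- function(omission_error, commission_error) {
  eo <- omission_error / 100
  ec <- commission_error / 100
  2 / (1 / (1 - eo) + 1 / (1 - ec))
}
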
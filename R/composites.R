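# Spectral indices, observation-level quality filtering, minimum-NBR
# compositing, and assembly of the 28-feature classification stack.

.feature_bands <- c("blue", "green", "red", "nir", "swirs", "swirl",
                    "ndvi", "nbr", "nbr2")

#' Spectral indices of one observation
#'
#' NDVI = (nir - red) / (nir + red); NBR = (nir - swirl) / (nir + swirl);
#' NBR2 = (swirs - swirl) / (swirs + swirl). Zero denominators yield NA,
#' flagging the observation for exclusion.
#'
#' @param bands named list (or named numeric vector) with elements `red`,
#'   `nir`, `swirs`, `swirl`; matrices and scalars are both accepted.
#' @return list with `ndvi`, `nbr`, `nbr2` of the same shape as the inputs.
#' @export
spectral_indices <- function(bands) {
  nd <- function(p, q) {
    den <- p + q
    out <- (p - q) / den
    out[den == 0] <- NA_real_
    out
  }
  list(ndvi = nd(bands$nir, bands$red),
       nbr = nd(bands$nir, bands$swirl),
       nbr2 = nd(bands$swirs, bands$swirl))
}

#' Quality filter for one observation
#'
#' Drops cloud-saturated pixels (swirl > 0.3 or nir > 0.33), water pixels
#' (red or nir < 0.005), and, for Landsat-5 acquisitions of 2001-2002
#' (`sensor_tag = "L5_early"`), diagonal-stripe artifacts with NBR2 below
#' -0.3. Undefined (NA) indices are also dropped.
#'
#' @param obs observation: list with `bands` (named list of matrices or
#'   scalars) and `sensor_tag`.
#' @return list with logical `keep` and character `reason` (`"ok"`,
#'   `"cloud"`, `"water"`, `"stripe"`, `"undefined"`), shaped like the bands.
#' @export
quality_filter <- function(obs) {
  b <- obs$bands
  idx <- spectral_indices(b)
  reason <- array("ok", dim = if (is.matrix(b$nir)) dim(b$nir) else length(b$nir))
  reason[b$swirl > 0.3 | b$nir > 0.33] <- "cloud"
  if (identical(obs$sensor_tag, "L5_early"))
    reason[reason == "ok" & !is.na(idx$nbr2) & idx$nbr2 < -0.3] <- "stripe"
  reason[b$red < 0.005 | b$nir < 0.005] <- "water"
  reason[is.na(idx$ndvi) | is.na(idx$nbr) | is.na(idx$nbr2)] <- "undefined"
  list(keep = reason == "ok", reason = reason)
}

#' Minimum-NBR yearly composite
#'
#' Reduces a year's surviving observations to the one with the lowest NBR
#' per pixel (the strongest fire signal); ties are broken toward the
#' earliest day by processing observations in ascending day order with a
#' strict improvement rule. Pixels with no surviving observation are
#' marked invalid.
#'
#' @param scenes list of observations (each: `day`, `sensor_tag`, `bands`
#'   as named list of matrices).
#' @return list with the six reflectance bands, `ndvi`, `nbr`, `nbr2`,
#'   `day` (day-of-year of the selected observation) and logical `valid`.
#' @export
min_nbr_composite <- function(scenes) {
  stopifnot(length(scenes) >= 1L)
  scenes <- scenes[order(vapply(scenes, `[[`, numeric(1), "day"))]
  dm <- dim(scenes[[1L]]$bands$nir)
  best_nbr <- matrix(Inf, dm[1L], dm[2L])
  out <- c(
    stats::setNames(lapply(.band_names, function(b) matrix(NA_real_, dm[1L], dm[2L])),
                    .band_names),
    list(ndvi = matrix(NA_real_, dm[1L], dm[2L]),
         nbr = matrix(NA_real_, dm[1L], dm[2L]),
         nbr2 = matrix(NA_real_, dm[1L], dm[2L]),
         day = matrix(NA_real_, dm[1L], dm[2L])))
  for (sc in scenes) {
    keep <- quality_filter(sc)$keep
    idx <- spectral_indices(sc$bands)
    upd <- keep & !is.na(idx$nbr) & idx$nbr < best_nbr
    if (!any(upd)) next
    best_nbr[upd] <- idx$nbr[upd]
    for (b in .band_names) out[[b]][upd] <- sc$bands[[b]][upd]
    out$ndvi[upd] <- idx$ndvi[upd]
    out$nbr[upd] <- idx$nbr[upd]
    out$nbr2[upd] <- idx$nbr2[upd]
    out$day[upd] <- sc$day
  }
  out$valid <- is.finite(best_nbr)
  out
}

#' Assemble the 28-feature classification stack
#'
#' Nine post-year features (six bands + NDVI, NBR, NBR2 of the minimum-NBR
#' observation), the same nine for the pre year, nine post-minus-pre
#' differences, and the date difference between compositing dates (the
#' post day gains a 365-day offset because the pre composite belongs to
#' the previous year).
#'
#' @param pre,post composites from [min_nbr_composite()] on the same grid.
#' @param year_offset_days calendar offset added to the post day (365).
#' @return list with `features` (array `[h, w, 28]`, named slices),
#'   `post_day`, and `valid` (both composites valid).
#' @export
build_feature_stack <- function(pre, post, year_offset_days = 365) {
  if (!identical(dim(pre$nir), dim(post$nir)))
    stop("pre and post composites are on different grids", call. = FALSE)
  dm <- dim(post$nir)
  nms <- c(paste0(.feature_bands, "_post"), paste0(.feature_bands, "_pre"),
           paste0(.feature_bands, "_diff"), "date_diff")
  feats <- array(NA_real_, dim = c(dm, 28L), dimnames = list(NULL, NULL, nms))
  for (b in .feature_bands) {
    feats[, , paste0(b, "_post")] <- post[[b]]
    feats[, , paste0(b, "_pre")] <- pre[[b]]
    feats[, , paste0(b, "_diff")] <- post[[b]] - pre[[b]]
  }
  feats[, , "date_diff"] <- (post$day + year_offset_days) - pre$day
  list(features = feats, post_day = post$day, valid = pre$valid & post$valid)
}

# Flatten the feature array to a data.frame over the given cell indices.
feature_rows <- function(stack, idx) {
  nms <- dimnames(stack$features)[[3L]]
  out <- as.data.frame(lapply(seq_along(nms), function(k) {
    sl <- stack$features[, , k]
    sl[idx]
  }))
  names(out) <- nms
  out
}
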
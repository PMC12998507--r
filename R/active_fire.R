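# Active-fire fusion: footprint rasterization, Voronoi date assignment,
# contiguity-based pixel appending, and previous-year relocation.

#' Rasterize active-fire detections
#'
#' Each record paints the pixels whose centers fall inside the footprint
#' rectangle (`along_track_m` by `cross_track_m`) centered on the
#' detection. Overlapping records keep the earliest day. Records outside
#' the grid are skipped with a warning.
#'
#' @param records data.frame with `x`, `y` (meters), `day`,
#'   `along_track_m`, `cross_track_m`; footprints are a per-record
#'   attribute, so mixed-sensor years (1000-m and 375-m) are handled.
#' @param dim grid dimensions `c(nrow, ncol)`.
#' @param pixel_size pixel edge, meters.
#' @return raster of day-of-year values (NA where no detection).
#' @export
rasterize_active_fires <- function(records, dim, pixel_size = 30) {
  h <- dim[1L]; w <- dim[2L]
  out <- matrix(NA_real_, h, w)
  if (is.null(records) || nrow(records) == 0L) return(out)
  oob <- records$x < 0 | records$x > w * pixel_size |
    records$y < 0 | records$y > h * pixel_size
  if (any(oob)) {
    warning(sum(oob), " active-fire record(s) outside the grid skipped")
    records <- records[!oob, , drop = FALSE]
  }
  records <- records[order(records$day), , drop = FALSE]  # earliest day wins
  for (i in seq_len(nrow(records))) {
    cs <- which(abs((seq_len(w) - 0.5) * pixel_size - records$x[i]) <=
                  records$along_track_m[i] / 2)
    rs <- which(abs((seq_len(h) - 0.5) * pixel_size - records$y[i]) <=
                  records$cross_track_m[i] / 2)
    blk <- out[rs, cs, drop = FALSE]
    blk[is.na(blk)] <- records$day[i]
    out[rs, cs] <- blk
  }
  out
}

#' Reassign burn dates by nearest active fire (Voronoi)
#'
#' Every burned pixel receives the day of its nearest active-fire record
#' (Euclidean distance between the pixel center and the detection);
#' distance ties resolve to the earlier day. With no records, pixels keep
#' their composite-derived day and are flagged low-confidence.
#'
#' @param burned logical raster.
#' @param records active-fire data.frame (`x`, `y`, `day`) for the year.
#' @param composite_day fallback day raster (minimum-NBR observation day).
#' @param pixel_size pixel edge, meters.
#' @return list with `day` raster and logical `low_confidence`.
#' @export
assign_dates_voronoi <- function(burned, records, composite_day = NULL,
                                 pixel_size = 30) {
  day <- matrix(NA_real_, nrow(burned), ncol(burned))
  if (is.null(records) || nrow(records) == 0L) {
    if (!is.null(composite_day)) day[burned] <- composite_day[burned]
    return(list(day = day, low_confidence = burned))
  }
  records <- records[order(records$day), , drop = FALSE]  # tie -> earlier day
  idx <- which(burned)
  q <- pixel_xy(idx, dim(burned), pixel_size)
  nn <- nearest_point(q, cbind(records$x, records$y))
  day[idx] <- records$day[nn$which]
  list(day = day, low_confidence = matrix(FALSE, nrow(burned), ncol(burned)))
}

#' Append active-fire pixels to burned patches
#'
#' Active-fire pixels Queen's-case connected to an existing burned patch
#' are amended to it unless dominated by water (annual water cover at or
#' above `water_threshold`). Applied iteratively so chains of active-fire
#' pixels attach. Never removes pixels.
#'
#' @param burned logical raster.
#' @param af_day active-fire day raster ([rasterize_active_fires()]).
#' @param water_cover annual water-cover fraction raster.
#' @param water_threshold water-cover fraction above which a pixel is
#'   considered water-dominated (0.8).
#' @return augmented logical raster (a superset of `burned`).
#' @export
append_af_pixels <- function(burned, af_day, water_cover,
                             water_threshold = 0.8) {
  if (!identical(dim(burned), dim(af_day)) ||
      !identical(dim(burned), dim(water_cover)))
    stop("rasters are not aligned", call. = FALSE)
  candidate <- !is.na(af_day) & water_cover < water_threshold
  out <- burned
  repeat {
    add <- candidate & !out & dilate3(out)
    if (!any(add)) break
    out <- out | add
  }
  out
}

#' Relocate late-detected burned pixels to the previous year
#'
#' A pixel detected in year t is reassigned to year t-1 when (1) at least
#' one previous-year active fire lies within `max_dist_m` (inclusive) and
#' (2) the nearest previous-year active fire is strictly closer than any
#' active fire of the processing year.
#'
#' @param burned logical raster of year-t detections.
#' @param records_prev,records_curr active-fire data.frames of years t-1
#'   and t.
#' @param max_dist_m proximity bound for condition 1 (5 km).
#' @param pixel_size pixel edge, meters.
#' @return logical raster: TRUE where the pixel moves to year t-1.
#' @export
relocate_year <- function(burned, records_prev, records_curr,
                          max_dist_m = 5000, pixel_size = 30) {
  out <- matrix(FALSE, nrow(burned), ncol(burned))
  if (!any(burned) || is.null(records_prev) || nrow(records_prev) == 0L)
    return(out)
  idx <- which(burned)
  q <- pixel_xy(idx, dim(burned), pixel_size)
  d_prev <- nearest_point(q, cbind(records_prev$x, records_prev$y))$dist
  d_curr <- if (is.null(records_curr) || nrow(records_curr) == 0L)
    rep(Inf, length(idx))
  else nearest_point(q, cbind(records_curr$x, records_curr$y))$dist
  out[idx] <- d_prev <= max_dist_m & d_prev < d_curr
  out
}
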
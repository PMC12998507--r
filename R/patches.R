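# Spatiotemporal flood-fill fire patches, tile-window merging, and
# overwintering-fire flagging.

# Patch attribute table from a label raster and day raster.
make_patch_table <- function(labels, day, pixel_size, year = NA_integer_) {
  k <- max(labels)
  if (k == 0L)
    return(data.frame(patch_id = integer(0), year = integer(0),
                      n_pixels = integer(0), start_day = numeric(0),
                      end_day = numeric(0), duration = numeric(0),
                      size_ha = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0)))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  xy <- pixel_xy(idx, dim(labels), pixel_size)
  dv <- day[idx]
  agg <- function(v, f) as.numeric(tapply(v, lab, f))
  data.frame(
    patch_id = seq_len(k), year = year,
    n_pixels = as.integer(tabulate(lab, nbins = k)),
    start_day = agg(dv, min), end_day = agg(dv, max),
    duration = agg(dv, max) - agg(dv, min),
    size_ha = tabulate(lab, nbins = k) * pixel_size^2 / 1e4,
    centroid_x = agg(xy[, 1L], mean), centroid_y = agg(xy[, 2L], mean))
}

#' Cluster dated burned pixels into fire patches
#'
#' Temporal flood fill: two burned pixels belong to the same patch iff
#' they are connected by a chain of neighbor pairs, each with a burn-day
#' difference of at most `cutoff_days`. Neighborhood is Queen's-case
#' 8-connectivity, extended to any pixel pair within `bridge_buffer_m`
#' (center-to-center) so that patches separated by narrow rivers or other
#' barriers are kept together.
#'
#' @param day raster of burn day-of-year (NA = unburned).
#' @param burned optional logical raster; defaults to `!is.na(day)`. A
#'   burned pixel without a day is an error.
#' @param cutoff_days maximum day difference between neighbors (16; the
#'   trial range was 12-24 days).
#' @param bridge_buffer_m bridging distance, meters (150).
#' @param pixel_size pixel edge, meters.
#' @param year optional year recorded in the patch table.
#' @return object of class `fire_patches`: `labels` raster (0 =
#'   background), `day`, `pixel_size`, `year`, and a `patches` table with
#'   size, duration, start/end day and centroid.
#' @export
cluster_patches <- function(day, burned = NULL, cutoff_days = 16,
                            bridge_buffer_m = 150, pixel_size = 30,
                            year = NA_integer_) {
  if (is.null(burned)) burned <- !is.na(day)
  undated <- which(burned & is.na(day))
  if (length(undated) > 0L)
    stop("burned pixels without a burn day at cell indices: ",
         paste(utils::head(undated, 10L), collapse = ", "), call. = FALSE)
  radius_px <- max(sqrt(2), bridge_buffer_m / pixel_size)
  labels <- cluster_cells(burned, day = day, radius_px = radius_px,
                          cutoff = cutoff_days)
  structure(list(labels = labels, day = day, pixel_size = pixel_size,
                 year = year,
                 patches = make_patch_table(labels, day, pixel_size, year)),
            class = "fire_patches")
}

#' Cluster per tile window and merge duplicated patches
#'
#' Processes the raster in square tiles, clustering each tile within a
#' rolling window of nine tiles centered on it, keeps the patches that
#' touch the center tile, and merges duplicates (patches from neighboring
#' windows sharing pixels). For patches smaller than one tile span the
#' result is identical to clustering the whole raster at once.
#'
#' @param day burn-day raster.
#' @param tile_px tile edge, pixels.
#' @inheritParams cluster_patches
#' @return a `fire_patches` object on the full grid.
#' @export
merge_tiles <- function(day, tile_px = 32L, cutoff_days = 16,
                        bridge_buffer_m = 150, pixel_size = 30,
                        year = NA_integer_) {
  h <- nrow(day); w <- ncol(day)
  nt_r <- ceiling(h / tile_px); nt_c <- ceiling(w / tile_px)
  burned <- !is.na(day)
  labels <- matrix(0L, h, w)
  next_id <- 0L
  pieces <- list()  # pixel index sets per provisional patch
  for (ti in seq_len(nt_r)) for (tj in seq_len(nt_c)) {
    rw <- (max(1L, (ti - 2L) * tile_px + 1L)):(min(h, (ti + 1L) * tile_px))
    cw <- (max(1L, (tj - 2L) * tile_px + 1L)):(min(w, (tj + 1L) * tile_px))
    sub <- day[rw, cw, drop = FALSE]
    if (!any(!is.na(sub))) next
    cp <- cluster_patches(sub, cutoff_days = cutoff_days,
                          bridge_buffer_m = bridge_buffer_m,
                          pixel_size = pixel_size)
    ctr_r <- ((ti - 1L) * tile_px + 1L):min(h, ti * tile_px)
    ctr_c <- ((tj - 1L) * tile_px + 1L):min(w, tj * tile_px)
    in_ctr <- matrix(FALSE, length(rw), length(cw))
    in_ctr[rw %in% ctr_r, cw %in% ctr_c] <- TRUE
    keep_ids <- setdiff(unique(cp$labels[in_ctr]), 0L)
    for (pid in keep_ids) {
      sel <- which(cp$labels == pid)
      rr <- rw[((sel - 1L) %% length(rw)) + 1L]
      cc <- cw[((sel - 1L) %/% length(rw)) + 1L]
      next_id <- next_id + 1L
      pieces[[next_id]] <- (cc - 1L) * h + rr  # global cell indices
    }
  }
  if (next_id == 0L)
    return(cluster_patches(day, cutoff_days = cutoff_days,
                           bridge_buffer_m = bridge_buffer_m,
                           pixel_size = pixel_size, year = year))
  # Merge provisional patches that share pixels (duplicates across windows).
  parent <- seq_len(next_id)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  owner <- integer(h * w)
  for (p in seq_len(next_id)) {
    for (cell in pieces[[p]]) {
      if (owner[cell] == 0L) owner[cell] <- p
      else {
        ra <- find(owner[cell]); rb <- find(p)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(next_id), find, integer(1L))
  relab <- match(roots, unique(roots))
  for (p in seq_len(next_id)) labels[pieces[[p]]] <- relab[p]
  structure(list(labels = labels, day = day, pixel_size = pixel_size,
                 year = year,
                 patches = make_patch_table(labels, day, pixel_size, year)),
            class = "fire_patches")
}

#' Flag fires of overwintering origin
#'
#' A patch is flagged when it starts before the main fire season (July 1:
#' day 182, 183 in leap years, exclusive) and its pixel set lies within
#' `max_dist_m` (edge-to-edge, i.e. nearest pixel centers) of a
#' previous-year patch. The linkage records the nearest qualifying origin
#' patch and, when a peat mask is given, whether peatland is present in
#' the corridor between the two patches (the elliptical buffer around the
#' closest pixel pair).
#'
#' @param patches,patches_prev `fire_patches` objects for years t and t-1.
#' @param peat_mask optional logical peat raster.
#' @param max_dist_m reappearance vicinity, meters (1000).
#' @param leap is year t a leap year (moves the boundary to day 183).
#' @return the `patches` table of year t with `overwintering`, `origin_id`,
#'   `origin_dist_m` and `peat_corridor` columns added.
#' @export
flag_overwintering <- function(patches, patches_prev, peat_mask = NULL,
                               max_dist_m = 1000, leap = FALSE) {
  stopifnot(inherits(patches, "fire_patches"),
            inherits(patches_prev, "fire_patches"))
  tab <- patches$patches
  boundary <- if (leap) 183 else 182
  tab$overwintering <- FALSE
  tab$origin_id <- NA_integer_
  tab$origin_dist_m <- NA_real_
  tab$peat_corridor <- NA
  if (nrow(tab) == 0L || max(patches_prev$labels) == 0L) return(tab)
  px <- patches$pixel_size
  for (i in seq_len(nrow(tab))) {
    if (tab$start_day[i] >= boundary) next
    cur_idx <- which(patches$labels == tab$patch_id[i])
    cur_xy <- pixel_xy(cur_idx, dim(patches$labels), px)
    best <- list(d = Inf, id = NA_integer_, a = NULL, b = NULL)
    for (pid in seq_len(max(patches_prev$labels))) {
      prev_idx <- which(patches_prev$labels == pid)
      prev_xy <- pixel_xy(prev_idx, dim(patches_prev$labels), px)
      nn <- nearest_point(cur_xy, prev_xy)
      j <- which.min(nn$dist)
      if (nn$dist[j] < best$d)
        best <- list(d = nn$dist[j], id = pid, a = cur_xy[j, ],
                     b = prev_xy[nn$which[j], ])
    }
    tab$origin_dist_m[i] <- best$d
    if (best$d <= max_dist_m) {
      tab$overwintering[i] <- TRUE
      tab$origin_id[i] <- best$id
      if (!is.null(peat_mask)) {
        pq <- pixel_xy(which(peat_mask), dim(peat_mask), px)
        da <- sqrt((pq[, 1L] - best$a[1L])^2 + (pq[, 2L] - best$a[2L])^2)
        db <- sqrt((pq[, 1L] - best$b[1L])^2 + (pq[, 2L] - best$b[2L])^2)
        tab$peat_corridor[i] <- any(da + db <= best$d + 2 * max_dist_m)
      }
    }
  }
  tab
}

#' Patch size summaries
#'
#' Sizes in hectares (pixels x 0.09 ha at 30 m) with a large-fire flag at
#' the 1000-ha threshold and per-year counts.
#'
#' @param patches a `fire_patches` object or a patch table.
#' @param large_ha large-fire threshold, hectares.
#' @return list with the augmented `patches` table (`size_class`, `large`)
#'   and a per-year `counts` table.
#' @export
patch_summaries <- function(patches, large_ha = 1000) {
  tab <- if (inherits(patches, "fire_patches")) patches$patches else patches
  if (nrow(tab) == 0L)
    return(list(patches = tab, counts = data.frame(year = integer(0),
                                                   n = integer(0),
                                                   n_large = integer(0))))
  tab$large <- tab$size_ha > large_ha
  tab$size_class <- cut(tab$size_ha, c(0, 10, 100, 1000, Inf),
                        labels = c("<10 ha", "10-100 ha", "100-1000 ha",
                                   ">1000 ha"))
  counts <- do.call(rbind, lapply(split(tab, tab$year), function(d)
    data.frame(year = d$year[1L], n = nrow(d), n_large = sum(d$large))))
  rownames(counts) <- NULL
  list(patches = tab, counts = counts)
}
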
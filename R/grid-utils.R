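# Internal helpers for the planar 30-m matrix grid.
#
# Rasters are plain numeric/logical matrices [nrow = grid height, ncol =
# grid width]. Pixel centers sit at x = (col - 0.5) * pixel_size,
# y = (row - 0.5) * pixel_size, so Euclidean metric thresholds (150 m,
# 1 km, 2 km, 5 km) translate directly to pixel units.

#' Pixel-center coordinates of raster cells
#'
#' @param idx integer vector of cell indices (column-major, as returned by
#'   [which()] on a matrix) or a two-column `cbind(row, col)` matrix.
#' @param dim `c(nrow, ncol)` of the raster.
#' @param pixel_size pixel edge length in meters.
#' @return two-column matrix of x, y coordinates in meters.
#' @keywords internal
pixel_xy <- function(idx, dim, pixel_size = 30) {
  if (is.matrix(idx)) {
    rc <- idx
  } else {
    rc <- cbind(((idx - 1L) %% dim[1L]) + 1L, ((idx - 1L) %/% dim[1L]) + 1L)
  }
  cbind(x = (rc[, 2L] - 0.5) * pixel_size, y = (rc[, 1L] - 0.5) * pixel_size)
}

# Minimum Euclidean distance from each query point to a reference point set,
# plus the index of the nearest reference. Ties resolved toward the lowest
# reference index, so callers control tie-breaks by pre-sorting `ref`.
nearest_point <- function(query, ref, chunk = 4096L) {
  nq <- nrow(query)
  out_d <- numeric(nq)
  out_i <- integer(nq)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    dx <- outer(query[s:e, 1L], ref[, 1L], "-")
    dy <- outer(query[s:e, 2L], ref[, 2L], "-")
    d2 <- dx * dx + dy * dy
    wi <- max.col(-d2, ties.method = "first")
    out_i[s:e] <- wi
    out_d[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), wi)])
  }
  list(dist = out_d, which = out_i)
}

# Distance from every raster cell to the nearest TRUE cell of `mask`
# (meters); Inf where mask is empty.
dist_to_mask <- function(mask, pixel_size = 30) {
  d <- matrix(Inf, nrow(mask), ncol(mask))
  idx_ref <- which(mask)
  if (length(idx_ref) == 0L) return(d)
  ref <- pixel_xy(idx_ref, dim(mask), pixel_size)
  all_xy <- pixel_xy(seq_along(mask), dim(mask), pixel_size)
  d[] <- nearest_point(all_xy, ref)$dist
  d
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  if (abs(dr) >= h || abs(dc) >= w) return(out)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# 3x3 binary dilation / erosion (square structuring element).
dilate3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out | shift_mat(mask, dr, dc, FALSE)
  }
  out
}

erode3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out & shift_mat(mask, dr, dc, TRUE)
  }
  out
}

# Cluster TRUE cells of a mask into connected components. Two cells are
# linked when their center distance is <= radius_px pixels (radius_px =
# sqrt(2) gives plain Queen's-case 8-connectivity) and, if `day` is given,
# when |day_i - day_j| <= cutoff. Returns a matrix of component labels
# (0 = background), relabeled 1..k in first-appearance order.
cluster_cells <- function(mask, day = NULL, radius_px = sqrt(2), cutoff = Inf) {
  h <- nrow(mask); w <- ncol(mask)
  n <- sum(mask)
  lab <- matrix(0L, h, w)
  if (n == 0L) return(lab)
  serial <- matrix(0L, h, w)
  serial[mask] <- seq_len(n)
  idx <- which(mask)
  dvals <- if (is.null(day)) rep(0, n) else day[mask]
  parent <- seq_len(n)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving in this frame
      i <- parent[i]
    }
    i
  }
  r <- floor(radius_px + 1e-9)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr * offs$dr + offs$dc * offs$dc <= radius_px^2 + 1e-9, ]
  offs <- offs[offs$dr > 0L | (offs$dr == 0L & offs$dc > 0L), , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    a <- serial
    b <- shift_mat(serial, offs$dr[k], offs$dc[k], 0L)
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    ai <- a[sel]; bi <- b[sel]
    ok <- abs(dvals[ai] - dvals[bi]) <= cutoff
    ai <- ai[ok]; bi <- bi[ok]
    for (e in seq_along(ai)) {
      ra <- uf_find(ai[e])
      rb <- uf_find(bi[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), uf_find, integer(1L))
  lab[idx] <- match(roots, unique(roots))
  lab
}
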
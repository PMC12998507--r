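# Area-conserving peatland downscaling and peat-fire attribution.

#' Downscale a coarse peatland area map by index thresholding
#'
#' Within each coarse unit, fine pixels are selected in decreasing order
#' of the peatland plausibility index until their cumulative area matches
#' the coarse peat area (rounded to the nearest achievable pixel count).
#' Ties and equal indices resolve by deterministic pixel order (ascending
#' cell index), so the result is reproducible. Coarse units may be given
#' either as a regular block size or as a labeled-region raster, which
#' also supports large irregular units.
#'
#' @param peat_index fine-resolution index raster in [0, 1].
#' @param coarse_area coarse peat areas, m^2: a matrix of block values
#'   (with `cell_px` giving the block edge in fine pixels) or, with
#'   `regions`, a named/numeric vector per region label.
#' @param cell_px edge of one coarse cell in fine pixels.
#' @param regions optional integer raster of coarse-unit labels.
#' @param pixel_size fine pixel edge, meters.
#' @return logical fine-resolution peat mask.
#' @export
downscale_peat <- function(peat_index, coarse_area, cell_px = NULL,
                           regions = NULL, pixel_size = 30) {
  h <- nrow(peat_index); w <- ncol(peat_index)
  px_area <- pixel_size^2
  if (is.null(regions)) {
    stopifnot(!is.null(cell_px))
    regions <- matrix(0L, h, w)
    n_cc <- ceiling(w / cell_px)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      regions[i, j] <- (ceiling(i / cell_px) - 1L) * n_cc + ceiling(j / cell_px)
    }
    areas <- as.vector(t(coarse_area))  # row-major to match label order
  } else {
    areas <- coarse_area
  }
  out <- matrix(FALSE, h, w)
  for (rid in sort(unique(as.vector(regions)))) {
    if (rid == 0L) next  # unlabeled cells take no part
    cells <- which(regions == rid)
    target <- if (!is.null(names(areas))) areas[[as.character(rid)]]
              else areas[[rid]]
    if (target > length(cells) * px_area + 1e-6)
      stop("coarse peat area exceeds unit area for region ", rid,
           call. = FALSE)
    k <- round(target / px_area)
    if (k <= 0L) next
    ord <- cells[order(-peat_index[cells], cells)]
    out[ord[seq_len(min(k, length(ord)))]] <- TRUE
  }
  out
}

#' Classify burned pixels as peat or non-peat fires
#'
#' @param burned logical burned raster (one year) or a list of them.
#' @param peat_mask logical peat raster on the same grid.
#' @param labels optional patch label raster; adds per-patch peat
#'   fractions.
#' @param pixel_size pixel edge, meters.
#' @return list with `peat_fire` raster(s), `peat_ba_ha` and
#'   `total_ba_ha` per year, `peat_fraction` per year, and optionally a
#'   `patch_peat_fraction` vector.
#' @export
classify_peat_fires <- function(burned, peat_mask, labels = NULL,
                                pixel_size = 30) {
  one_year <- !is.list(burned)
  yrs <- if (one_year) list(burned) else burned
  for (b in yrs) if (!identical(dim(b), dim(peat_mask)))
    stop("burned and peat rasters are misaligned", call. = FALSE)
  ha <- pixel_size^2 / 1e4
  peat_fire <- lapply(yrs, function(b) b & peat_mask)
  total <- vapply(yrs, sum, numeric(1)) * ha
  peat <- vapply(peat_fire, sum, numeric(1)) * ha
  out <- list(peat_fire = if (one_year) peat_fire[[1L]] else peat_fire,
              total_ba_ha = total, peat_ba_ha = peat,
              peat_fraction = ifelse(total > 0, peat / total, NA_real_))
  if (!is.null(labels) && max(labels) > 0L) {
    k <- max(labels)
    pf <- peat_fire[[1L]]
    out$patch_peat_fraction <- vapply(seq_len(k), function(pid) {
      sel <- labels == pid
      n <- sum(sel)
      if (n == 0L) NA_real_ else sum(pf & sel) / n
    }, numeric(1))
  }
  out
}

#' Agreement of peat-fire labels with a reference point set
#'
#' @param peat_fire logical peat-fire raster.
#' @param burned logical burned raster (points off it are excluded and
#'   counted separately).
#' @param points data.frame with `x`, `y` (meters) and logical/0-1
#'   `is_peat` reference labels.
#' @param pixel_size pixel edge, meters.
#' @return list with `n_used`, `n_matching`, `agreement` fraction, and
#'   `n_off_burned`.
#' @export
agreement_with_reference <- function(peat_fire, burned, points,
                                     pixel_size = 30) {
  col <- pmin(pmax(ceiling(points$x / pixel_size), 1L), ncol(burned))
  row <- pmin(pmax(ceiling(points$y / pixel_size), 1L), nrow(burned))
  cell <- (col - 1L) * nrow(burned) + row
  on_burn <- burned[cell]
  used <- which(on_burn)
  match_ok <- peat_fire[cell[used]] == as.logical(points$is_peat[used])
  list(n_used = length(used), n_matching = sum(match_ok),
       agreement = if (length(used) > 0L) mean(match_ok) else NA_real_,
       n_off_burned = sum(!on_burn))
}
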
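# Classification refinement: seed confirmation, spectral region growing,
# seed-count patch filtering, and morphological cleanup.

#' Confirm burned seeds
#'
#' Seeds are classified-burned pixels whose burn probability strictly
#' exceeds the threshold (the mean probability of the burned training
#' class, carried on the classifier as `seed_threshold`).
#'
#' @param p_b probability raster.
#' @param classified logical raster of classified-burned pixels.
#' @param seed_threshold threshold in (0, 1).
#' @return logical seed raster.
#' @export
confirm_seeds <- function(p_b, classified, seed_threshold) {
  stopifnot(seed_threshold > 0, seed_threshold < 1)
  classified & !is.na(p_b) & p_b > seed_threshold
}

# The unrestrictive spectral disjunction admitting a pixel to the growing
# region: high burn probability, or a burn-consistent spectral change, or
# a strongly burned post state.
growth_rule <- function(p_b, stack) {
  f <- function(nm) stack$features[, , nm]
  r1 <- !is.na(p_b) & p_b >= 0.40
  r2 <- f("nbr2_post") <= 0.06 & f("nbr2_diff") <= 0.005 &
    f("red_diff") >= 0.04 & f("nir_diff") <= -0.003
  r3 <- f("nbr2_post") <= 0 & f("nbr2_diff") <= 0.01 & f("red_post") <= 0.03
  r2[is.na(r2)] <- FALSE
  r3[is.na(r3)] <- FALSE
  (r1 | r2 | r3) & stack$valid
}

#' Grow the burned region from confirmed seeds
#'
#' Iterates to convergence: a candidate pixel is added when it satisfies
#' the spectral disjunction (P_b >= 40%, or NBR2post <= 0.06 & NBR2diff <=
#' 0.005 & Reddiff >= 0.04 & NIRdiff <= -0.003, or NBR2post <= 0 &
#' NBR2diff <= 0.01 & Redpost <= 0.03), lies within `vicinity_m` of the
#' nearest confirmed seed, and is 8-connected to the current burned
#' region. The converged mask is a fixed point: it does not depend on
#' visit order, and enlarging the seed set can only enlarge it.
#'
#' @param seeds logical seed raster ([confirm_seeds()]).
#' @param stack feature stack of the year.
#' @param p_b probability raster.
#' @param vicinity_m maximum distance to a confirmed seed, meters (2 km).
#' @param pixel_size pixel edge, meters.
#' @return logical refined burned mask (a superset of the seeds).
#' @export
grow_region <- function(seeds, stack, p_b, vicinity_m = 2000, pixel_size = 30) {
  if (!any(seeds)) return(seeds)
  eligible <- growth_rule(p_b, stack) &
    dist_to_mask(seeds, pixel_size) <= vicinity_m
  region <- seeds
  repeat {
    grown <- dilate3(region) & eligible & !region
    if (!any(grown)) break
    region <- region | grown
  }
  region
}

#' Discard burned patches with too few seeds
#'
#' Connected components (Queen's case) of the burned mask containing
#' fewer than `min_seeds` confirmed seeds are removed.
#'
#' @param mask logical burned raster.
#' @param seeds logical seed raster.
#' @param min_seeds minimum seed count for a patch to survive (4).
#' @return filtered logical raster.
#' @export
filter_patches_by_seeds <- function(mask, seeds, min_seeds = 4L) {
  lab <- cluster_cells(mask)
  if (max(lab) == 0L) return(mask)
  seed_counts <- tabulate(lab[seeds & mask], nbins = max(lab))
  keep <- which(seed_counts >= min_seeds)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Morphological cleanup of the burned mask
#'
#' Applies dilation-then-erosion followed by erosion-then-dilation with a
#' 3 x 3 structuring element (90 m at 30-m pixels). The first pass fills
#' single-pixel holes; the second removes isolated pixels and thin
#' protrusions. The operator order follows the reference procedure's own
#' parenthetical definitions ("opening" = dilation then erosion, "closing"
#' = erosion then dilation), which swap the standard terminology; the
#' literal sequence dilate-erode-erode-dilate is applied.
#'
#' @param mask logical raster.
#' @return cleaned logical raster.
#' @export
morphological_cleanup <- function(mask) {
  m <- erode3(dilate3(mask))   # fills holes ("opening" as defined upstream)
  dilate3(erode3(m))           # removes isolated pixels ("closing")
}
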
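# Synthetic fire landscapes with known ground truth.
#
# The generator emulates, on a planar 30-m grid, the inputs of a
# high-latitude burned-area and peat-fire analysis: multi-date six-band
# reflectance stacks with cloud and water contamination, active-fire point
# detections sampled along each scar's progression front, a peatland
# plausibility index with a coarse area constraint, field combustion plots,
# and an annual climate table with a long-term baseline. Reflectance is
# piecewise-constant archetypes (vegetated / burned / water / cloud) plus
# Gaussian noise: the downstream classifiers need separability and
# controlled confusion, not radiative-transfer realism.

# Surface-reflectance archetypes (blue, green, red, nir, swirs, swirl).
# Vegetated NIR is kept below the 0.33 cloud-filter threshold; burned
# pixels satisfy the region-growing spectral clauses (NBR2post <= 0.06,
# Reddiff >= 0.04, NIRdiff <= -0.003) by construction.
.archetypes <- list(
  vegetated = c(blue = 0.050, green = 0.080, red = 0.050, nir = 0.300,
                swirs = 0.180, swirl = 0.120),
  burned    = c(blue = 0.040, green = 0.050, red = 0.100, nir = 0.120,
                swirs = 0.150, swirl = 0.220),
  cloud     = c(blue = 0.450, green = 0.450, red = 0.450, nir = 0.450,
                swirs = 0.350, swirl = 0.400)
)

.band_names <- c("blue", "green", "red", "nir", "swirs", "swirl")

#' Configuration for a synthetic fire landscape
#'
#' Defaults define the study conditions used throughout the test suite: a
#' 128 x 128 grid of 30-m pixels (3.84 km on a side), three analysis years,
#' three main scars per year plus one planted overwintering scar per year
#' pair and one planted late-season scar per year (the relocation cases),
#' 15% per-observation cloud cover, 5% open water, and scar placement
#' steered toward a peat overlap of 43.6% of burned area.
#'
#' @param grid_height,grid_width grid dimensions in pixels (>= 32).
#' @param pixel_size pixel edge length, meters.
#' @param years number of analysis years.
#' @param cloud_fraction probability that a pixel observation is cloud.
#' @param n_scars_per_year main (summer) scars per year.
#' @param scar_size_range ellipse semi-axis range, pixels.
#' @param water_fraction fraction of the grid under open water.
#' @param peat_fraction fraction of the grid that is true peatland.
#' @param target_peat_overlap scar placement steers the overall fraction of
#'   burned pixels falling on peat toward this value.
#' @param n_field_plots rows of the field combustion table.
#' @param n_obs multi-date observations per year (March-November window).
#' @param coarse_cell_px edge, in fine pixels, of one coarse peat-area cell.
#' @param rng_seed integer seed; a fixed seed gives byte-identical outputs.
#' @return an object of class `peat_sim_config`.
#' @export
sim_config <- function(grid_height = 128L, grid_width = 128L, pixel_size = 30,
                       years = 3L, cloud_fraction = 0.15,
                       n_scars_per_year = 3L, scar_size_range = c(5, 10),
                       water_fraction = 0.05, peat_fraction = 0.30,
                       target_peat_overlap = 0.436,
                       n_field_plots = 894L, n_obs = 8L,
                       coarse_cell_px = 32L, rng_seed = 1L) {
  if (grid_height < 32L || grid_width < 32L)
    stop("grid dimensions must be at least 32 pixels", call. = FALSE)
  fr <- c(cloud_fraction, water_fraction, peat_fraction, target_peat_overlap)
  if (any(fr < 0) || any(fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (years < 1L) stop("need at least one analysis year", call. = FALSE)
  structure(list(
    grid_height = as.integer(grid_height), grid_width = as.integer(grid_width),
    pixel_size = pixel_size, years = as.integer(years),
    cloud_fraction = cloud_fraction, n_scars_per_year = as.integer(n_scars_per_year),
    scar_size_range = scar_size_range, water_fraction = water_fraction,
    peat_fraction = peat_fraction, target_peat_overlap = target_peat_overlap,
    n_field_plots = as.integer(n_field_plots), n_obs = as.integer(n_obs),
    coarse_cell_px = as.integer(coarse_cell_px), rng_seed = as.integer(rng_seed)
  ), class = "peat_sim_config")
}

# Gaussian-smoothed white-noise field, standardized to mean 0, sd 1.
smooth_field <- function(h, w, scale_px = 12) {
  k1 <- function(n) {
    x <- seq_len(n)
    K <- exp(-0.5 * (outer(x, x, "-") / scale_px)^2)
    K / rowSums(K)
  }
  f <- k1(h) %*% matrix(stats::rnorm(h * w), h, w) %*% t(k1(w))
  (f - mean(f)) / stats::sd(f)
}

# Pixels of an ellipse scar plus each pixel's burn day (center-out spread).
scar_pixels <- function(cx, cy, rx, ry, theta, ignition, duration,
                        dim, pixel_size) {
  xy <- pixel_xy(seq_len(prod(dim)), dim, pixel_size)
  dx <- xy[, 1L] - cx
  dy <- xy[, 2L] - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / (rx * pixel_size)
  v <- (-dx * sin(theta) + dy * cos(theta)) / (ry * pixel_size)
  r <- sqrt(u^2 + v^2)
  idx <- which(r <= 1)
  list(idx = idx, day = ignition + floor(pmin(r[idx], 1) * duration))
}

# Approximate edge-to-edge distance between two ellipse scars (center
# distance minus the larger semi-axes; conservative).
scar_gap <- function(a, b) {
  sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2) -
    (max(a$rx, a$ry) + max(b$rx, b$ry)) * a$pixel_size
}

#' Simulate dated reflectance scene stacks with known ground truth
#'
#' Generates, for years `0..cfg$years` (year 0 is unburned and serves only
#' as the pre-year compositing source), `cfg$n_obs` six-band scenes on
#' days 75-320, plus the ground truth needed to score every downstream
#' stage: per-year scar masks and per-pixel burn days, a peat index with
#' its coarse area constraint, the water-cover raster, active-fire records,
#' planted overwintering scars (ignition before July 1 within 1 km of a
#' previous-year scar), and planted late-season scars whose burn days fall
#' after the last observation of their true year so that they surface in
#' the next year's composites (the relocation cases).
#'
#' @param cfg a [sim_config()].
#' @return list with `scenes` (per year, a list of observations each
#'   holding `day`, `year`, `sensor_tag` and a 6-band list of matrices)
#'   and `truth` (class `peat_sim_truth`).
#' @export
simulate_scenes <- function(cfg) {
  stopifnot(inherits(cfg, "peat_sim_config"))
  set.seed(cfg$rng_seed)
  h <- cfg$grid_height; w <- cfg$grid_width; px <- cfg$pixel_size
  dims <- c(h, w)
  obs_days <- round(seq(75, 320, length.out = cfg$n_obs))
  last_obs <- max(obs_days)

  # -- static landscape -----------------------------------------------------
  water_mask <- smooth_field(h, w, scale_px = 6)
  water_mask <- water_mask >= stats::quantile(water_mask, 1 - cfg$water_fraction)
  water_cover <- matrix(stats::runif(h * w, 0, 0.2), h, w)
  water_cover[water_mask] <- stats::runif(sum(water_mask), 0.85, 1.0)

  peat_index <- smooth_field(h, w, scale_px = 14)
  peat_index <- matrix(rank(peat_index) / (h * w), h, w)   # uniform in (0,1]
  peat_truth <- peat_index >= stats::quantile(peat_index, 1 - cfg$peat_fraction)
  cpx <- cfg$coarse_cell_px
  n_cr <- ceiling(h / cpx); n_cc <- ceiling(w / cpx)
  coarse_area <- matrix(0, n_cr, n_cc)
  for (i in seq_len(n_cr)) for (j in seq_len(n_cc)) {
    rows <- ((i - 1L) * cpx + 1L):min(i * cpx, h)
    cols <- ((j - 1L) * cpx + 1L):min(j * cpx, w)
    coarse_area[i, j] <- sum(peat_truth[rows, cols]) * px^2
  }

  # -- scar placement -------------------------------------------------------
  scars <- list()
  burned_total <- 0; burned_peat <- 0
  place <- function(kind, year, near = NULL) {
    best <- NULL; best_score <- Inf
    rr <- cfg$scar_size_range
    for (try in 1:200) {
      rx <- stats::runif(1, rr[1], rr[2]); ry <- stats::runif(1, rr[1], rr[2])
      rmax <- max(rx, ry) * px
      if (is.null(near)) {
        if (stats::runif(1) < 0.5) {   # propose from peat-dense ground half
          ci <- sample(which(peat_truth), 1L)        # the time, so the
          cxy <- pixel_xy(ci, dims, px)              # greedy sees both
          cx <- cxy[1L]; cy <- cxy[2L]               # overlap regimes
          if (cx < rmax + px || cx > w * px - rmax - px ||
              cy < rmax + px || cy > h * px - rmax - px) next
        } else {
          cx <- stats::runif(1, rmax + px, w * px - rmax - px)
          cy <- stats::runif(1, rmax + px, h * px - rmax - px)
        }
      } else {
        gap <- stats::runif(1, 450, 800)
        ang <- stats::runif(1, 0, 2 * pi)
        dd <- gap + rmax + max(near$rx, near$ry) * px
        cx <- near$cx + dd * cos(ang); cy <- near$cy + dd * sin(ang)
        if (cx < rmax + px || cx > w * px - rmax - px ||
            cy < rmax + px || cy > h * px - rmax - px) next
      }
      cand <- list(cx = cx, cy = cy, rx = rx, ry = ry,
                   theta = stats::runif(1, 0, pi), pixel_size = px)
      ok <- TRUE
      for (s in scars) {
        g <- scar_gap(cand, s)
        min_gap <- if (!is.null(near) && identical(s, near)) 420 else
          if (s$year == year) 300 else 250
        if (g < min_gap) { ok <- FALSE; break }
      }
      if (!ok) next
      sp <- scar_pixels(cx, cy, rx, ry, cand$theta, 0, 1, dims, px)
      if (any(water_mask[sp$idx])) next
      new_total <- burned_total + length(sp$idx)
      new_peat <- burned_peat + sum(peat_truth[sp$idx])
      score <- abs(new_peat / new_total - cfg$target_peat_overlap)
      if (score < best_score) { best_score <- score; best <- cand }
    }
    if (is.null(best)) return(NULL)
    sp <- scar_pixels(best$cx, best$cy, best$rx, best$ry, best$theta,
                      0, 1, dims, px)
    burned_total <<- burned_total + length(sp$idx)
    burned_peat <<- burned_peat + sum(peat_truth[sp$idx])
    best$year <- year
    best$kind <- kind
    best
  }

  for (y in seq_len(cfg$years)) {
    if (y > 1L) {  # overwintering scar near a previous-year scar
      prev <- Filter(function(s) s$year == y - 1L && s$kind != "late", scars)
      if (length(prev) > 0L) {
        org <- prev[[1L + (y %% length(prev))]]
        s <- place("overwinter", y, near = org)
        if (!is.null(s)) {
          s$ignition <- round(stats::runif(1, 155, 175))  # before July 1
          s$duration <- round(stats::runif(1, 14, 22))
          s$origin <- org$id
          s$id <- length(scars) + 1L
          scars[[s$id]] <- s
        }
      }
    }
    for (k in seq_len(cfg$n_scars_per_year)) {
      s <- place("main", y)
      if (is.null(s)) next
      s$ignition <- round(stats::runif(1, 186, 255))      # July-September
      s$duration <- round(stats::runif(1, 14, 24))
      s$id <- length(scars) + 1L
      scars[[s$id]] <- s
    }
    if (y < cfg$years) {  # late-season scar, invisible in its true year
      s <- place("late", y)
      if (!is.null(s)) {
        s$ignition <- last_obs + 11L                      # day 331, window end
        s$duration <- 3L
        s$id <- length(scars) + 1L
        scars[[s$id]] <- s
      }
    }
  }

  # -- truth rasters per true year -----------------------------------------
  scar_mask <- lapply(seq_len(cfg$years), function(y) matrix(FALSE, h, w))
  burn_day <- lapply(seq_len(cfg$years), function(y) matrix(NA_real_, h, w))
  for (s in scars) {
    sp <- scar_pixels(s$cx, s$cy, s$rx, s$ry, s$theta, s$ignition, s$duration,
                      dims, px)
    scar_mask[[s$year]][sp$idx] <- TRUE
    burn_day[[s$year]][sp$idx] <- sp$day
  }

  # -- active fires along the progression front ----------------------------
  af <- list()
  for (s in scars) {
    sp <- scar_pixels(s$cx, s$cy, s$rx, s$ry, s$theta, s$ignition, s$duration,
                      dims, px)
    days <- seq(s$ignition, s$ignition + s$duration, by = 4L)
    for (d in days) {
      front <- sp$idx[abs(sp$day - d) <= 2]
      if (length(front) == 0L) next
      pick <- front[unique(round(seq(1, length(front),
                                     length.out = min(3L, length(front)))))]
      xy <- pixel_xy(pick, dims, px)
      af[[length(af) + 1L]] <- data.frame(
        x = xy[, 1L] + stats::runif(length(pick), -10, 10),
        y = xy[, 2L] + stats::runif(length(pick), -10, 10),
        day = d, year = s$year,
        # one-pixel footprints: at desk scale the active-fire evidence is
        # matched to the 30-m mapping grid (full-size 375/1000-m footprint
        # painting is exercised separately in rasterize_active_fires)
        along_track_m = px, cross_track_m = px, scar_id = s$id)
    }
  }
  active_fires <- do.call(rbind, af)

  # -- predictor rasters and combustion truth ------------------------------
  f1 <- smooth_field(h, w, 14); f2 <- smooth_field(h, w, 14)
  f3 <- smooth_field(h, w, 14)
  depth_truth <- pmax(9.5 + 1.8 * f1 + 1.2 * f2 - 0.9 * f3 +
                        matrix(stats::rnorm(h * w, 0, 2.3), h, w), 0.5)
  below_truth <- pmax(310 * depth_truth + 100 +
                        matrix(stats::rnorm(h * w, 0, 880), h, w), 0)
  agb <- 1500 + 400 * smooth_field(h, w, 14)
  above_truth <- pmax(400 + 0.25 * (agb - 1500) + 20 * f2 +
                        matrix(stats::rnorm(h * w, 0, 120), h, w), 0)
  dict <- predictor_dictionary("depth")
  predictors <- stats::setNames(vector("list", length(dict) + 1L),
                                c(dict, "agb_biomass"))
  predictors[["dnbr"]] <- f1
  predictors[["cwd_summer"]] <- f2
  predictors[["water_table_depth"]] <- f3
  predictors[["agb_biomass"]] <- agb
  for (nm in names(predictors)) {
    if (is.null(predictors[[nm]])) predictors[[nm]] <- smooth_field(h, w, 10)
  }

  scar_df <- do.call(rbind, lapply(scars, function(s) data.frame(
    id = s$id, year = s$year, kind = s$kind, cx = s$cx, cy = s$cy,
    rx = s$rx, ry = s$ry, theta = s$theta, ignition = s$ignition,
    duration = s$duration, origin = if (is.null(s$origin)) NA_integer_ else s$origin)))

  truth <- structure(list(
    cfg = cfg, dim = dims, obs_days = obs_days, last_obs_day = last_obs,
    water_mask = water_mask, water_cover = water_cover,
    peat_index = peat_index, peat_mask = peat_truth,
    coarse_area = coarse_area,
    scar_mask = scar_mask, burn_day = burn_day, scars = scar_df,
    active_fires = active_fires,
    predictors = predictors, depth_truth = depth_truth,
    below_truth = below_truth, above_truth = above_truth,
    depth_noise_sd = 0.6, below_noise_sd = 637, above_noise_sd = 120
  ), class = "peat_sim_truth")

  # -- scene synthesis ------------------------------------------------------
  # A pixel looks burned in year y scenes if its scar belongs to year y and
  # its burn day has passed, or if it burned after the last observation of
  # year y-1 (late scars persist into the next growing season).
  scenes <- vector("list", cfg$years + 1L)
  names(scenes) <- paste0("year", 0:cfg$years)
  for (y in 0:cfg$years) {
    carry <- matrix(FALSE, h, w)
    if (y >= 2L) {
      prev_late <- !is.na(burn_day[[y - 1L]]) & burn_day[[y - 1L]] > last_obs
      carry <- carry | prev_late
    }
    yr_scenes <- vector("list", length(obs_days))
    for (k in seq_along(obs_days)) {
      d <- obs_days[k]
      burned_now <- carry
      if (y >= 1L)
        burned_now <- burned_now | (!is.na(burn_day[[y]]) & burn_day[[y]] <= d)
      cloud <- matrix(stats::runif(h * w) < cfg$cloud_fraction, h, w)
      bands <- lapply(.band_names, function(bn) {
        m <- matrix(.archetypes$vegetated[[bn]], h, w)
        m[burned_now] <- .archetypes$burned[[bn]]
        m <- m + matrix(stats::rnorm(h * w, 0, 0.01), h, w)
        m[cloud] <- .archetypes$cloud[[bn]] + stats::rnorm(sum(cloud), 0, 0.01)
        if (bn %in% c("red", "nir", "swirs", "swirl", "blue", "green"))
          m[water_mask] <- stats::runif(sum(water_mask), 0.001, 0.0045)
        pmax(m, 0)
      })
      names(bands) <- .band_names
      yr_scenes[[k]] <- list(day = d, year = y, sensor_tag = "L8",
                             bands = bands)
    }
    scenes[[y + 1L]] <- yr_scenes
  }

  list(scenes = scenes, truth = truth)
}

#' Simulate a field combustion-plot table
#'
#' Emulates a literature compilation of combustion measurements across
#' northern fire regions, with provenance proportions 285:568:41
#' (Alaska:Canada:Siberia). Burn depth follows a sparse linear link on 3 of
#' the 42 candidate predictors; belowground carbon combustion is
#' `310 g C m^-2 per cm` of depth plus a region (site) offset and noise
#' calibrated so that the sample Pearson correlation between depth and
#' belowground combustion is 0.75. Aboveground combustion depends on
#' biomass and canopy cover.
#'
#' @param cfg a [sim_config()] (`n_field_plots`, `rng_seed`).
#' @param noise_scale multiplies every noise standard deviation; 0 gives
#'   the deterministic limit (within-region depth-combustion r of 1).
#' @return data.frame with `region`, `burn_depth`, `belowground_cc`,
#'   `aboveground_cc` and one column per predictor (42 shared + biomass).
#' @export
simulate_field_plots <- function(cfg, noise_scale = 1) {
  stopifnot(inherits(cfg, "peat_sim_config"))
  n <- cfg$n_field_plots
  if (n < 50L) stop("need at least 50 field plots", call. = FALSE)
  set.seed(cfg$rng_seed + 1000L)
  prop <- c(Alaska = 285, Canada = 568, Siberia = 41) / 894
  counts <- round(n * prop)
  counts[1L] <- n - sum(counts[-1L])
  region <- rep(names(counts), counts)
  dict <- predictor_dictionary("depth")
  X <- matrix(stats::rnorm(n * length(dict)), n, length(dict),
              dimnames = list(NULL, dict))
  agb <- 1500 + 400 * stats::rnorm(n)
  # Depth: sparse linear link plus noise sized so that a boosted model
  # explains about half of the variance, as field compilations show.
  depth_sd_noise <- 2.3
  depth <- pmax(9.5 + 1.8 * X[, "dnbr"] + 1.2 * X[, "cwd_summer"] -
                  0.9 * X[, "water_table_depth"] +
                  noise_scale * stats::rnorm(n, 0, depth_sd_noise), 0.5)
  site <- c(Alaska = -250, Canada = 100, Siberia = 350)[region]
  # Residual sd chosen so that r(depth, belowground) = 0.75:
  # extra_var = (alpha * sd_depth)^2 * (1/r^2 - 1), minus the site-term
  # variance under the 285:568:41 provenance mix.
  alpha <- 310
  var_depth <- 1.8^2 + 1.2^2 + 0.9^2 + depth_sd_noise^2
  var_site <- sum(prop * c(-250, 100, 350)^2) - sum(prop * c(-250, 100, 350))^2
  var_extra <- (alpha^2 * var_depth) * (1 / 0.75^2 - 1)
  sd_resid <- sqrt(max(var_extra - var_site, 0))
  below <- pmax(alpha * depth + site +
                  noise_scale * stats::rnorm(n, 0, sd_resid), 0)
  above <- pmax(400 + 0.25 * (agb - 1500) + 20 * X[, "cwd_summer"] +
                  noise_scale * stats::rnorm(n, 0, 120), 0)
  out <- data.frame(region = region, burn_depth = depth,
                    belowground_cc = below, aboveground_cc = unname(above))
  out <- cbind(out, as.data.frame(X), agb_biomass = agb)
  rownames(out) <- NULL
  out
}

#' Simulate an annual summer climate table with a long-term baseline
#'
#' Peat burned area follows an exponential link on the climatic
#' water-deficit z-score, `BA = exp(a + b z) * lognormal noise`; the
#' Drought Code co-varies positively and PDSI negatively with the deficit.
#' Monthly values carry a fixed seasonal offset pattern so that the
#' June-September mean recovers the annual summer value exactly. A
#' three-zone panel generated from the full causal graph (water deficit and
#' minimum temperature exogenous; DC and PDSI intermediate; total and peat
#' burned area and belowground combustion endogenous with zone random
#' intercepts) supports the structural equation model.
#'
#' @param cfg a [sim_config()] (seed only).
#' @param years analysis years (23, mirroring 2001-2023).
#' @param baseline_years years of the long-term baseline (66, 1958-2023).
#' @param a,b exponential-link intercept and slope (the generator truth).
#' @param noise_sd lognormal noise sd of the burned-area link.
#' @return object of class `peat_climate`: `monthly`, `baseline_monthly`,
#'   `annual`, `zones`, `coefficients`.
#' @export
simulate_climate_series <- function(cfg, years = 2001:2023,
                                    baseline_years = 1958:2023,
                                    a = 0, b = 0.9, noise_sd = 0.35) {
  stopifnot(inherits(cfg, "peat_sim_config"))
  set.seed(cfg$rng_seed + 2000L)
  vars <- c(wd = 100, dc = 250, dmc = 40, pdsi = 0, soil_moisture = 0.30,
            tmin = 8)
  sds <- c(wd = 25, dc = 60, dmc = 15, pdsi = 1.7, soil_moisture = 0.05,
           tmin = 1.5)
  draw_years <- function(yrs) {
    n <- length(yrs)
    z <- stats::rnorm(n)                       # water-deficit driver
    m <- cbind(
      wd = vars[["wd"]] + sds[["wd"]] * z,
      dc = vars[["dc"]] + sds[["dc"]] * (0.8 * z + 0.6 * stats::rnorm(n)),
      dmc = vars[["dmc"]] + sds[["dmc"]] * (0.75 * z + 0.66 * stats::rnorm(n)),
      pdsi = vars[["pdsi"]] + sds[["pdsi"]] * (-0.85 * z + 0.53 * stats::rnorm(n)),
      soil_moisture = vars[["soil_moisture"]] +
        sds[["soil_moisture"]] * (-0.7 * z + 0.71 * stats::rnorm(n)),
      tmin = vars[["tmin"]] + sds[["tmin"]] * (0.3 * z + 0.95 * stats::rnorm(n)))
    list(m = m, z = z)
  }
  base <- draw_years(baseline_years)
  study <- draw_years(years)
  # z-scores of the study years against the baseline sample statistics
  z_wd <- (study$m[, "wd"] - mean(base$m[, "wd"])) / stats::sd(base$m[, "wd"])
  peat_ba <- exp(a + b * z_wd + stats::rnorm(length(years), 0, noise_sd))
  total_ba <- peat_ba * 3 * exp(stats::rnorm(length(years), 0, 0.15))
  annual <- data.frame(year = years, study$m, peat_ba = peat_ba,
                       total_ba = total_ba)

  # Monthly tables (summer months only; fixed seasonal offsets).
  mk_monthly2 <- function(yrs, m) {
    off <- c(-0.6, 0.5, 0.4, -0.3)
    out <- do.call(rbind, lapply(seq_along(yrs), function(i) {
      d <- as.data.frame(lapply(colnames(m), function(v)
        m[i, v] + off * sds[[v]] * 0.2))
      names(d) <- colnames(m)
      cbind(year = yrs[i], month = c(6L, 7L, 8L, 9L), d)
    }))
    rownames(out) <- NULL
    out
  }
  monthly <- mk_monthly2(years, study$m)
  baseline_monthly <- mk_monthly2(baseline_years, base$m)

  # Three-zone standardized panel from the causal graph.
  zones <- c("west", "central", "east")
  nz <- length(zones); ny <- length(years)
  zpan <- expand.grid(year = years, zone = zones, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(zpan)
  u_ba <- stats::rnorm(nz, 0, 0.3); u_peat <- stats::rnorm(nz, 0, 0.3)
  u_cc <- stats::rnorm(nz, 0, 0.3)
  zi <- as.integer(factor(zpan$zone, levels = zones))
  wd <- stats::rnorm(n); tmin <- stats::rnorm(n)
  dc <- 0.66 * wd - 0.30 * tmin + stats::rnorm(n, 0, 0.55)
  pdsi <- -0.85 * wd + stats::rnorm(n, 0, 0.55)
  e_common <- stats::rnorm(n, 0, 0.45)
  log_ba <- 0.60 * dc - 0.20 * pdsi + u_ba[zi] + e_common + stats::rnorm(n, 0, 0.2)
  log_peat_ba <- 0.45 * dc - 0.45 * pdsi + u_peat[zi] + e_common +
    stats::rnorm(n, 0, 0.2)
  bcc <- 0.40 * log_peat_ba + 0.30 * wd + 0.25 * tmin + u_cc[zi] +
    stats::rnorm(n, 0, 0.5)
  zpan <- cbind(zpan, wd = wd, tmin = tmin, dc = dc, pdsi = pdsi,
                log_ba = log_ba, log_peat_ba = log_peat_ba, bcc = bcc)

  structure(list(
    monthly = monthly, baseline_monthly = baseline_monthly,
    annual = annual, zones = zpan,
    coefficients = list(a = a, b = b, noise_sd = noise_sd, z_wd = z_wd)
  ), class = "peat_climate")
}
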
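# Shared fixtures and independent brute-force oracles.

# Small, fast simulation configuration for module tests.
small_cfg <- function(seed = 1L, ...) {
  sim_config(grid_height = 64L, grid_width = 64L, years = 2L,
             n_field_plots = 200L, rng_seed = seed, ...)
}

# One observation with given band values (matrices or scalars).
make_obs <- function(day = 150, sensor_tag = "L8", blue = 0.05, green = 0.08,
                     red = 0.05, nir = 0.30, swirs = 0.18, swirl = 0.12) {
  list(day = day, year = 1L, sensor_tag = sensor_tag,
       bands = list(blue = blue, green = green, red = red, nir = nir,
                    swirs = swirs, swirl = swirl))
}

# Minimal feature stack with constant slices, overridden per feature name.
make_stack <- function(h, w, overrides = list()) {
  nms <- c(paste0(peatfire:::.feature_bands, "_post"),
           paste0(peatfire:::.feature_bands, "_pre"),
           paste0(peatfire:::.feature_bands, "_diff"), "date_diff")
  defaults <- list(nbr2_post = 0.2, nbr2_diff = 0.1, red_diff = 0,
                   nir_diff = 0, red_post = 0.1, date_diff = 300)
  feats <- array(0, dim = c(h, w, 28L), dimnames = list(NULL, NULL, nms))
  for (nm in names(defaults)) feats[, , nm] <- defaults[[nm]]
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    feats[, , nm] <- v
  }
  list(features = feats, post_day = matrix(200, h, w),
       valid = matrix(TRUE, h, w))
}

# Partition equality of two label vectors (up to relabeling).
same_partition <- function(a, b) {
  u <- unique(cbind(a, b))
  nrow(u) == length(unique(a)) && nrow(u) == length(unique(b))
}

# Brute-force clustering oracle: pairwise adjacency + graph components.
oracle_cluster <- function(day, cutoff, radius_px) {
  idx <- which(!is.na(day))
  n <- length(idx)
  rc <- cbind((idx - 1) %% nrow(day) + 1, (idx - 1) %/% nrow(day) + 1)
  d2 <- as.matrix(stats::dist(rc))^2
  dd <- abs(outer(day[idx], day[idx], "-"))
  adj <- d2 <= radius_px^2 + 1e-9 & dd <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Brute-force 3x3 morphology oracle (direct neighborhood scan).
oracle_dilate <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rs <- max(1, i - 1):min(h, i + 1)
    cs <- max(1, j - 1):min(w, j + 1)
    out[i, j] <- any(m[rs, cs])
  }
  out
}

oracle_erode <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rs <- max(1, i - 1):min(h, i + 1)
    cs <- max(1, j - 1):min(w, j + 1)
    out[i, j] <- all(m[rs, cs])
  }
  out
}

# Brute-force nearest-record day assignment.
oracle_voronoi <- function(burned, records, pixel_size = 30) {
  day <- matrix(NA_real_, nrow(burned), ncol(burned))
  for (cell in which(burned)) {
    r <- (cell - 1) %% nrow(burned) + 1
    c <- (cell - 1) %/% nrow(burned) + 1
    x <- (c - 0.5) * pixel_size; y <- (r - 0.5) * pixel_size
    d <- sqrt((records$x - x)^2 + (records$y - y)^2)
    best <- which(d == min(d))
    day[cell] <- min(records$day[best])
  }
  day
}
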
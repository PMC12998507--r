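# Spectral indices, quality filters, minimum-NBR compositing, feature stack.

test_that("spectral indices evaluate the printed formulas", {
  i <- spectral_indices(list(red = 0.1, nir = 0.4, swirs = 0.3, swirl = 0.1))
  expect_equal(i$ndvi, 0.6)
  expect_equal(i$nbr2, 0.5)
  expect_equal(spectral_indices(list(red = 0.1, nir = 0.2, swirs = 0.3,
                                     swirl = 0.2))$nbr, 0)
  # zero denominator flags the value
  expect_true(is.na(spectral_indices(list(red = 0, nir = 0, swirs = 0.1,
                                          swirl = 0.1))$ndvi))
})

test_that("quality filter drops clouds, water and L5 stripes only", {
  keep1 <- function(...) quality_filter(make_obs(...))$keep
  expect_false(keep1(swirl = 0.35))                 # cloud: swirl cap
  expect_false(keep1(nir = 0.35))                   # cloud: nir cap
  expect_false(keep1(red = 0.002))                  # water
  expect_false(keep1(nir = 0.004))                  # water
  # NBR2 = -0.4 stripe artifact: dropped only for L5 2001-2002 scenes
  expect_true(keep1(swirl = 0.2, nir = 0.3, swirs = 6 / 70,
                    sensor_tag = "L8"))
  expect_false(keep1(swirl = 0.2, nir = 0.3, swirs = 6 / 70,
                     sensor_tag = "L5_early"))
  expect_true(keep1())                              # clean vegetated pixel
  r <- quality_filter(make_obs(swirl = 0.35))$reason
  expect_equal(as.vector(r), "cloud")
})

test_that("filter decision is unchanged whether indices come before or after", {
  set.seed(4)
  for (k in 1:50) {
    o <- make_obs(red = runif(1, 0, 0.4), nir = runif(1, 0, 0.4),
                  swirs = runif(1, 0.01, 0.4), swirl = runif(1, 0.01, 0.4),
                  sensor_tag = sample(c("L8", "L5_early"), 1))
    direct <- quality_filter(o)$keep
    # recompute from pre-computed indices: same decision
    idx <- spectral_indices(o$bands)
    manual <- !(o$bands$swirl > 0.3 || o$bands$nir > 0.33 ||
                  (o$sensor_tag == "L5_early" && idx$nbr2 < -0.3) ||
                  o$bands$red < 0.005 || o$bands$nir < 0.005 ||
                  is.na(idx$nbr))
    expect_equal(as.vector(direct), manual)
  }
})

test_that("minimum-NBR composite selects the lowest NBR, earliest day on ties", {
  m <- function(v) matrix(v, 1, 1)
  obs <- function(day, nir, swirl) make_obs(day = day, nir = m(nir),
                                            swirl = m(swirl), red = m(0.05),
                                            swirs = m(0.18), blue = m(0.05),
                                            green = m(0.08))
  # NBR sequence {0.3, -0.1, 0.2} -> the -0.1 observation
  sc <- list(obs(100, 0.26, 0.14), obs(150, 0.09, 0.11), obs(200, 0.18, 0.12))
  nbrs <- sapply(sc, function(o)
    (o$bands$nir - o$bands$swirl) / (o$bands$nir + o$bands$swirl))
  comp <- min_nbr_composite(sc)
  expect_equal(comp$nbr[1, 1], min(nbrs), tolerance = 1e-12)
  expect_equal(comp$day[1, 1], 150)
  # single observation: itself (compositing idempotence)
  one <- min_nbr_composite(sc[2])
  expect_equal(one$day[1, 1], 150)
  expect_equal(one$nir[1, 1], 0.09)
  # tie on NBR: earliest day wins
  tie <- list(obs(200, 0.20, 0.12), obs(150, 0.20, 0.12))
  expect_equal(min_nbr_composite(tie)$day[1, 1], 150)
  # no surviving observation -> invalid pixel
  bad <- min_nbr_composite(list(obs(100, 0.40, 0.35)))
  expect_false(bad$valid[1, 1])
})

test_that("feature stack holds 28 named features with exact differences", {
  m <- function(v) matrix(v, 2, 2)
  mk <- function(day, nbr2s) {
    o <- make_obs(day = day, blue = m(0.05), green = m(0.08), red = m(0.05),
                  nir = m(0.30), swirs = m(nbr2s), swirl = m(0.12))
    min_nbr_composite(list(o))
  }
  pre <- mk(200, 0.18)   # NBR2 = (0.18-0.12)/0.30 = 0.2
  post <- mk(180, 0.1326315789)
  st <- build_feature_stack(pre, post)
  expect_equal(dim(st$features)[3L], 28L)
  nbr2_pre <- (0.18 - 0.12) / 0.30
  nbr2_post <- (0.1326315789 - 0.12) / (0.1326315789 + 0.12)
  expect_equal(st$features[1, 1, "nbr2_diff"], nbr2_post - nbr2_pre,
               tolerance = 1e-9, ignore_attr = TRUE)
  # date difference spans the year boundary: 180 + 365 - 200 = 345
  expect_equal(st$features[1, 1, "date_diff"], 345, ignore_attr = TRUE)
  # identical composites: all difference features zero
  st0 <- build_feature_stack(pre, pre, year_offset_days = 0)
  diffs <- st0$features[, , grepl("_diff$", dimnames(st0$features)[[3]])]
  expect_true(all(diffs == 0))
  # grid mismatch
  pre3 <- mk(200, 0.18); pre3$nir <- matrix(0.3, 3, 3)
  expect_error(build_feature_stack(pre3, post), "different grids")
})

test_that("noiseless synthetic scars have negative NBR2 differences", {
  cfg <- small_cfg(seed = 9L, cloud_fraction = 0)
  sim <- simulate_scenes(cfg)
  comps <- lapply(0:1, function(y) min_nbr_composite(sim$scenes[[y + 1L]]))
  st <- build_feature_stack(comps[[1L]], comps[[2L]])
  tr <- sim$truth
  visible <- tr$scar_mask[[1L]] & tr$burn_day[[1L]] <= tr$last_obs_day
  d <- st$features[, , "nbr2_diff"][visible & st$valid]
  expect_true(all(d < 0))
})
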
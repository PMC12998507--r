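# Fire-patch clustering, tile merging, overwintering, size summaries.

test_that("the 16-day cutoff splits and the 150-m buffer bridges", {
  # collinear adjacent pixels, days 100 / 110 / 140 -> {100, 110} and {140}
  day <- matrix(NA_real_, 5, 5)
  day[3, 1:3] <- c(100, 110, 140)
  cp <- cluster_patches(day)
  expect_equal(max(cp$labels), 2L)
  expect_equal(cp$labels[3, 1], cp$labels[3, 2])
  expect_false(cp$labels[3, 2] == cp$labels[3, 3])
  # 4-pixel (120 m) gap: bridged at 150 m; 300-m gap: split
  day2 <- matrix(NA_real_, 5, 30)
  day2[3, 1:3] <- 150; day2[3, 8:10] <- 155    # gap cols 4..7
  expect_equal(max(cluster_patches(day2)$labels), 1L)
  day3 <- matrix(NA_real_, 5, 30)
  day3[3, 1:3] <- 150; day3[3, 14:16] <- 155   # 10-pixel (300 m) gap
  expect_equal(max(cluster_patches(day3)$labels), 2L)
  # undated burned pixel is an error
  expect_error(cluster_patches(day, burned = matrix(TRUE, 5, 5)), "burn day")
})

test_that("flood fill equals the brute-force transitive closure", {
  set.seed(21)
  for (k in 1:15) {
    day <- matrix(NA_real_, 48, 48)
    cells <- sample(48 * 48, 90)
    day[cells] <- sample(100:260, 90, replace = TRUE)
    cutoff <- sample(c(12, 16, 24), 1)
    cp <- cluster_patches(day, cutoff_days = cutoff)
    want <- oracle_cluster(day, cutoff, radius_px = 5)
    idx <- which(!is.na(day))
    expect_true(same_partition(cp$labels[idx], want))
  }
})

test_that("increasing the cutoff never increases the patch count", {
  set.seed(22)
  for (k in 1:8) {
    day <- matrix(NA_real_, 40, 40)
    cells <- sample(1600, 120)
    day[cells] <- sample(100:220, 120, replace = TRUE)
    counts <- sapply(c(12, 16, 24), function(co)
      max(cluster_patches(day, cutoff_days = co)$labels))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("tile-window merging reproduces whole-raster clustering", {
  set.seed(23)
  day <- matrix(NA_real_, 96, 96)
  # several compact scars, one straddling a tile boundary at col 32/33
  put <- function(r0, c0, d0) {
    for (dr in -4:4) for (dc in -4:4)
      if (dr^2 + dc^2 <= 17) day[r0 + dr, c0 + dc] <<- d0 + dr
  }
  put(20, 32, 150); put(60, 70, 180); put(80, 15, 120); put(40, 40, 200)
  whole <- cluster_patches(day)
  tiled <- merge_tiles(day, tile_px = 32L)
  idx <- which(!is.na(day))
  expect_true(same_partition(whole$labels[idx], tiled$labels[idx]))
  expect_equal(max(tiled$labels), max(whole$labels))
  expect_equal(sort(tiled$patches$n_pixels), sort(whole$patches$n_pixels))
})

test_that("overwintering needs both an early start and 1-km proximity", {
  mk <- function(r, cols, day1) {
    d <- matrix(NA_real_, 80, 80)
    d[r, cols] <- day1
    cluster_patches(d)
  }
  prev <- mk(40, 10:12, 250)   # previous-year patch, cols 10..12
  # starts June 15 (day 166), nearest previous pixel ~800 m away
  cur1 <- mk(40, 39:41, 166)   # col 39 center - col 12 center = 27 px = 810 m
  f1 <- flag_overwintering(cur1, prev)
  expect_true(f1$overwintering[1])
  expect_equal(f1$origin_id[1], 1L)
  # starts July 10: not flagged despite 200-m distance
  cur2 <- mk(40, 19:21, 191)
  expect_false(flag_overwintering(cur2, prev)$overwintering[1])
  # starts June 1 but 1.5 km away: not flagged
  cur3 <- mk(40, 63:65, 152)
  expect_false(flag_overwintering(cur3, prev)$overwintering[1])
  # leap years move the boundary to day 183
  cur4 <- mk(40, 19:21, 182)
  expect_true(flag_overwintering(cur4, prev, leap = TRUE)$overwintering[1])
  expect_false(flag_overwintering(cur4, prev, leap = FALSE)$overwintering[1])
  # peat corridor: peat between the two patches is detected
  peat <- matrix(FALSE, 80, 80); peat[40, 25:30] <- TRUE
  f5 <- flag_overwintering(cur1, prev, peat_mask = peat)
  expect_true(f5$peat_corridor[1])
})

test_that("patch sizes, durations and the large-fire threshold are exact", {
  day <- matrix(NA_real_, 20, 20)
  day[1:10, 1:10] <- 150; day[3, 3] <- 162   # 100 pixels, duration 12
  cp <- cluster_patches(day)
  expect_equal(cp$patches$n_pixels, 100L)
  expect_equal(cp$patches$size_ha, 9)        # 100 x 900 m^2 = 9 ha
  expect_equal(cp$patches$start_day, 150)
  expect_equal(cp$patches$end_day, 162)
  expect_equal(cp$patches$duration, 12)
  s <- patch_summaries(cp)
  expect_false(s$patches$large[1])
  # 11,112 pixels = 1000.08 ha: crosses the large-fire threshold
  big <- data.frame(patch_id = 1L, year = 2020L, n_pixels = 11112L,
                    start_day = 100, end_day = 150, duration = 50,
                    size_ha = 11112 * 0.09, centroid_x = 0, centroid_y = 0)
  expect_true(patch_summaries(big)$patches$large[1])
  # empty patch set
  empty <- cluster_patches(matrix(NA_real_, 5, 5))
  expect_equal(nrow(patch_summaries(empty)$patches), 0L)
})
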
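# Area-conserving peat downscaling and peat-fire attribution.

test_that("downscaling selects exactly the top-index pixels per coarse cell", {
  set.seed(31)
  idx <- matrix(runif(100), 10, 10)            # distinct indices
  # one coarse cell covering the block, 40% peat
  mask <- downscale_peat(idx, coarse_area = matrix(40 * 900, 1, 1),
                         cell_px = 10L)
  expect_equal(sum(mask), 40L)
  expect_true(all(idx[mask] >= sort(idx, decreasing = TRUE)[40]))
  # zero coarse area selects nothing
  expect_false(any(downscale_peat(idx, matrix(0, 1, 1), cell_px = 10L)))
  # equal indices: deterministic half by pixel order
  flat <- matrix(0.5, 10, 10)
  m1 <- downscale_peat(flat, matrix(50 * 900, 1, 1), cell_px = 10L)
  m2 <- downscale_peat(flat, matrix(50 * 900, 1, 1), cell_px = 10L)
  expect_equal(sum(m1), 50L)
  expect_identical(m1, m2)
  expect_true(all(which(m1) == 1:50))          # ascending cell order
  # area exceeding the cell is an error
  expect_error(downscale_peat(idx, matrix(101 * 900, 1, 1), cell_px = 10L),
               "exceeds")
})

test_that("area conservation holds within one pixel per coarse unit", {
  set.seed(32)
  idx <- matrix(runif(64 * 64), 64, 64)
  ca <- matrix(runif(16, 0, 16 * 16 * 900), 4, 4)
  mask <- downscale_peat(idx, ca, cell_px = 16L)
  for (i in 1:4) for (j in 1:4) {
    rows <- ((i - 1) * 16 + 1):(i * 16)
    cols <- ((j - 1) * 16 + 1):(j * 16)
    got <- sum(mask[rows, cols]) * 900
    expect_lte(abs(got - ca[i, j]), 900 / 2 + 1e-9)
  }
  # monotone: raising a selected pixel's index never deselects it
  sel <- which(mask)[1]
  idx2 <- idx; idx2[sel] <- 1.5
  expect_true(downscale_peat(idx2, ca, cell_px = 16L)[sel])
})

test_that("irregular labeled regions are supported", {
  set.seed(33)
  idx <- matrix(runif(100), 10, 10)
  reg <- matrix(1L, 10, 10); reg[6:10, ] <- 2L
  mask <- downscale_peat(idx, c(`1` = 10 * 900, `2` = 5 * 900), regions = reg)
  expect_equal(sum(mask[reg == 1L]), 10L)
  expect_equal(sum(mask[reg == 2L]), 5L)
})

test_that("peat-fire attribution counts fractions correctly", {
  burned <- matrix(FALSE, 10, 10); burned[1:5, 1:10] <- TRUE  # 50 pixels
  peat <- matrix(FALSE, 10, 10); peat[1:2, 1:10] <- TRUE      # 20 burned on peat
  out <- classify_peat_fires(burned, peat)
  expect_equal(out$peat_fraction, 0.4)
  expect_equal(out$total_ba_ha, 50 * 0.09)
  # empty peat mask: everything non-peat
  none <- classify_peat_fires(burned, matrix(FALSE, 10, 10))
  expect_equal(none$peat_ba_ha, 0)
  expect_error(classify_peat_fires(burned, matrix(FALSE, 5, 5)), "misaligned")
  # per-patch fractions through a label raster
  lab <- matrix(0L, 10, 10); lab[1:5, 1:10] <- 1L
  withlab <- classify_peat_fires(burned, peat, labels = lab)
  expect_equal(withlab$patch_peat_fraction, 0.4)
})

test_that("reference-point agreement reproduces the quoted fraction", {
  # synthetic stand-in for a visually interpreted reference point set:
  # 4274 points on burned pixels, 4237 with matching labels
  set.seed(34)
  n <- 4274
  burned <- matrix(TRUE, 70, 70)
  peat_fire <- matrix(FALSE, 70, 70); peat_fire[, 1:35] <- TRUE
  cells <- sample(70 * 70, n, replace = TRUE)
  x <- ((cells - 1) %/% 70 + 0.5) * 30
  y <- ((cells - 1) %% 70 + 0.5) * 30
  lab <- peat_fire[cells]
  flip <- sample(n, n - 4237)
  lab[flip] <- !lab[flip]
  ag <- agreement_with_reference(peat_fire, burned,
                                 data.frame(x = x, y = y, is_peat = lab))
  expect_equal(ag$n_used, 4274L)
  expect_equal(ag$n_matching, 4237L)
  expect_equal(round(ag$agreement, 4), 0.9913)
  # all match / none match
  ag1 <- agreement_with_reference(peat_fire, burned,
                                  data.frame(x = x, y = y,
                                             is_peat = peat_fire[cells]))
  expect_equal(ag1$agreement, 1)
  ag0 <- agreement_with_reference(peat_fire, burned,
                                  data.frame(x = x, y = y,
                                             is_peat = !peat_fire[cells]))
  expect_equal(ag0$agreement, 0)
  # points off the burned mask are excluded and counted
  nb <- matrix(FALSE, 70, 70)
  ag_off <- agreement_with_reference(peat_fire, nb,
                                     data.frame(x = x[1:5], y = y[1:5],
                                                is_peat = lab[1:5]))
  expect_equal(ag_off$n_off_burned, 5L)
  expect_true(is.na(ag_off$agreement))
})
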
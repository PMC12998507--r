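# Matern kernel, covariance posteriors, Nystrom approximation, and
# annual-total uncertainty.

# Random pixel cloud; the default span stays within the correlation
# cutoff (batches are tile-local), keeping the kernel strictly positive.
cloud <- function(n, seed, span = 15000) {
  set.seed(seed)
  cbind(runif(n, 0, span), runif(n, 0, span))
}

test_that("Matern-3/2 kernel evaluates its closed form", {
  expect_equal(matern32(0, 25000), 1)
  expect_equal(matern32(25000, 25000), (1 + sqrt(3)) * exp(-sqrt(3)),
               tolerance = 1e-12)
  expect_equal(matern32(1e9, 25000, cutoff_m = Inf), 0, tolerance = 1e-12)
  # hard cutoff beyond the decay length
  expect_equal(matern32(25001, 25000), 0)
  expect_gt(matern32(24999, 25000), 0)
  # monotone decay within the cutoff
  d <- seq(0, 25000, length.out = 50)
  expect_true(all(diff(matern32(d, 25000)) < 0))
  expect_error(matern32(10, -1), "positive")
})

test_that("posterior covariance follows the printed identities", {
  x <- cloud(6, 51, span = 10000)
  # D = 0: posterior collapses to zero (k - k k^-1 k)
  cm0 <- covariance_matrices(x, sigma_cc = 0, pixel_area = 900)
  expect_lt(max(abs(cm0$k_posterior)), 1e-8)
  # D -> infinity: posterior approaches k
  cmI <- covariance_matrices(x, sigma_cc = 1e8, pixel_area = 900)
  expect_lt(max(abs(cmI$k_posterior - cmI$k)), 1e-4)
  # posterior diagonal never exceeds the prior (kernel) diagonal
  cm <- covariance_matrices(x, sigma_cc = 0.5, pixel_area = 900)
  expect_true(all(diag(cm$k_posterior) <= diag(cm$k) + 1e-12))
  expect_true(isSymmetric(cm$k_posterior))
})

test_that("two-point posterior matches the closed-form 2x2 inversion", {
  l <- 25000
  x <- rbind(c(0, 0), c(l, 0))   # d = l
  s2 <- 0.7^2 * 900^2            # equal noise
  cm <- covariance_matrices(x, sigma_cc = 0.7, pixel_area = 900,
                            length_scale = l)
  k <- matern32(l, l)
  K <- matrix(c(1, k, k, 1), 2, 2)
  prior <- K + diag(s2, 2)
  want <- K - K %*% solve(prior) %*% K
  expect_equal(cm$k_posterior, want, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Nystrom is exact at m = n and its error shrinks with m", {
  x <- cloud(200, 52)
  K <- peatfire:::kernel_matrix(x, 25000)
  set.seed(52)
  full <- nystrom_approx(x, m = 200L, length_scale = 25000)
  expect_lt(norm(full$reconstruct() - K, "F") / norm(K, "F"), 1e-8)
  set.seed(52)
  r1 <- nystrom_approx(x, m = 1L, length_scale = 25000)
  expect_lte(qr(r1$reconstruct())$rank, 1L)
  # Frobenius error non-increasing in m (averaged over seeds for sampling noise)
  err <- function(m) mean(sapply(1:5, function(s) {
    set.seed(52 + s)
    ny <- nystrom_approx(x, m = m, length_scale = 25000)
    norm(ny$reconstruct() - K, "F")
  }))
  errs <- sapply(c(10L, 50L, 100L, 200L), err)
  expect_true(all(diff(errs) <= 0.02 * errs[1] + 1e-9))
})

test_that("annual totals propagate variance through the posterior", {
  # near-independent pixels (tiny length scale): total variance equals the
  # sum of pixelwise posterior variances
  x <- cloud(40, 53)
  sig <- 0.9
  u <- annual_uncertainty(cc = rep(3000, 40), coords = x, sigma_cc = sig,
                          pixel_area = 900, length_scale = 1e-6)
  cm <- covariance_matrices(x, sig, 900, length_scale = 1e-6)
  diag_oracle <- sum((sig * 900)^2 * diag(cm$k_posterior))
  expect_equal(u$var_g2, diag_oracle, tolerance = 1e-6)
  # two perfectly correlated, equal-noise pixels: total sd is twice the
  # single-pixel sd, not sqrt(2) times
  x2 <- rbind(c(0, 0), c(0.001, 0))
  u2 <- annual_uncertainty(cc = rep(3000, 2), coords = x2, sigma_cc = sig,
                           pixel_area = 900)
  u1 <- annual_uncertainty(cc = 3000, coords = rbind(c(0, 0)), sigma_cc = sig,
                           pixel_area = 900)
  expect_equal(u2$sd_g_c / u1$sd_g_c, 2, tolerance = 1e-3)
  # zero burned pixels
  u0 <- annual_uncertainty(cc = numeric(0), coords = cbind(numeric(0),
                                                           numeric(0)),
                           sigma_cc = sig)
  expect_equal(u0$var_g2, 0)
  # the mean residual acts as a bias correction on the total
  ub <- annual_uncertainty(cc = rep(3000, 2), coords = x2, sigma_cc = sig,
                           mu_res = 10, pixel_area = 900)
  expect_equal(ub$total_g_c, (3000 - 10) * 900 * 2)
})

test_that("the Nystrom path agrees with the exact path", {
  x <- cloud(150, 54)
  exact <- annual_uncertainty(rep(2500, 150), x, sigma_cc = 0.8,
                              pixel_area = 900, method = "exact")
  set.seed(54)
  ny_full <- annual_uncertainty(rep(2500, 150), x, sigma_cc = 0.8,
                                pixel_area = 900, method = "nystrom", m = 150L)
  expect_equal(ny_full$var_g2, exact$var_g2, tolerance = 1e-6)
  set.seed(54)
  ny <- annual_uncertainty(rep(2500, 150), x, sigma_cc = 0.8,
                           pixel_area = 900, method = "nystrom", m = 60L)
  expect_lt(abs(ny$sd_g_c - exact$sd_g_c) / exact$sd_g_c, 0.15)
  # spatial correlation raises the total variance over the independent limit
  indep <- annual_uncertainty(rep(2500, 150), x, sigma_cc = 0.8,
                              pixel_area = 900, length_scale = 1e-6)
  expect_gt(exact$var_g2, indep$var_g2)
})
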
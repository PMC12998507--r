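# Matern-3/2 Gaussian-process propagation of combustion-model residual
# uncertainty to annual emission totals, with a Nystrom low-rank
# approximation for large pixel sets.
#
# Residuals of the combustion model are taken as N(mu_res, sigma_CC,res^2);
# each burned pixel i carries a scaled emission variance
# sigma_i^2 = (sigma_CC,i * A_i)^2, entering the heteroscedastic noise
# D = diag(sigma_1^2, ..., sigma_n^2). The prior covariance is K + D and
# the posterior is K - K (K + D)^-1 K, both built from the Matern-3/2
# kernel with a hard correlation cutoff (spatial correlation ignored
# beyond the cutoff distance). The cutoff technically breaks exact
# positive semi-definiteness, so a small jitter floor is applied where a
# factorization requires it.

#' Matern-3/2 kernel value
#'
#' k(d) = (1 + sqrt(3) d / l) exp(-sqrt(3) d / l), set to zero beyond the
#' correlation cutoff.
#'
#' @param distance_m distance(s), meters (>= 0).
#' @param length_scale decay length l, meters (25 km by default).
#' @param cutoff_m distance beyond which correlation is ignored; defaults
#'   to the length scale.
#' @return kernel value(s) in [0, 1].
#' @export
matern32 <- function(distance_m, length_scale = 25000, cutoff_m = length_scale) {
  if (length_scale <= 0) stop("length scale must be positive", call. = FALSE)
  s <- sqrt(3) * distance_m / length_scale
  out <- (1 + s) * exp(-s)
  out[distance_m > cutoff_m] <- 0
  out
}

# Dense kernel matrix over pixel coordinates (n x 2 meters).
kernel_matrix <- function(coords, length_scale = 25000,
                          cutoff_m = length_scale, coords2 = NULL) {
  if (is.null(coords2)) {
    d <- as.matrix(stats::dist(coords))
  } else {
    d <- sqrt(outer(coords[, 1L], coords2[, 1L], "-")^2 +
                outer(coords[, 2L], coords2[, 2L], "-")^2)
  }
  matern32(d, length_scale, cutoff_m)
}

#' Prior and posterior covariance of pixel emissions
#'
#' `k_prior = K + D` with heteroscedastic noise `D = diag((sigma_CC,i *
#' A_i)^2)`; `k_posterior = K - K (K + D)^-1 K`. A singular prior (possible
#' only with zero noise and duplicated points) receives a logged
#' regularization jitter.
#'
#' @param coords n x 2 matrix of pixel centers, meters.
#' @param sigma_cc per-pixel combustion residual sd, g C m^-2 (recycled).
#' @param pixel_area pixel area(s), m^2.
#' @param length_scale,cutoff_m kernel parameters.
#' @return list with `k`, `k_prior`, `k_posterior`, `D` (diagonal vector,
#'   g^2 C^2) and `jitter` (0 when none was needed).
#' @export
covariance_matrices <- function(coords, sigma_cc, pixel_area = 900,
                                length_scale = 25000, cutoff_m = length_scale) {
  n <- nrow(coords)
  stopifnot(n >= 1L)
  K <- kernel_matrix(coords, length_scale, cutoff_m)
  Dv <- (rep_len(sigma_cc, n) * rep_len(pixel_area, n))^2
  prior <- K + diag(Dv, n)
  jitter <- 0
  inv <- tryCatch(solve(prior, K), error = function(e) NULL)
  while (is.null(inv)) {
    jitter <- if (jitter == 0) 1e-8 else jitter * 100
    inv <- tryCatch(solve(prior + diag(jitter, n), K),
                    error = function(e) NULL)
    if (jitter > 1) stop("prior covariance unfactorizable", call. = FALSE)
  }
  if (jitter > 0)
    message("covariance_matrices: applied jitter ", jitter,
            " to a singular prior")
  post <- K - K %*% inv
  post <- (post + t(post)) / 2
  list(k = K, k_prior = prior, k_posterior = post, D = Dv, jitter = jitter)
}

#' Nystrom low-rank approximation of the kernel matrix
#'
#' Approximates `K ~ K_nm K_mm^-1 K_mn` from `m` inducing points sampled
#' uniformly without replacement (seeded by the caller's RNG state),
#' returned in factored form so the full n x n matrix is never
#' materialized. An ill-conditioned `K_mm` falls back to a pseudo-inverse
#' with a logged tolerance.
#'
#' @param coords n x 2 pixel centers, meters.
#' @param m number of inducing points (1000 per batch at full scale).
#' @param length_scale,cutoff_m kernel parameters.
#' @return list with `Knm` (n x m), `Kmm_inv` (m x m), `inducing`
#'   (indices), and `reconstruct()` returning the dense approximation
#'   (small n only).
#' @export
nystrom_approx <- function(coords, m, length_scale = 25000,
                           cutoff_m = length_scale) {
  n <- nrow(coords)
  stopifnot(m >= 1L, m <= n)
  ind <- sort(sample.int(n, m))
  Knm <- kernel_matrix(coords, length_scale, cutoff_m,
                       coords2 = coords[ind, , drop = FALSE])
  Kmm <- Knm[ind, , drop = FALSE]
  # K_mm is near-singular whenever inducing points are dense relative to
  # the length scale, so invert through an eigenvalue-truncated
  # pseudo-inverse rather than a raw solve.
  e <- eigen(Kmm, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  keep <- e$values > tol
  if (!all(keep))
    message("nystrom_approx: pseudo-inverse of K_mm, dropped ",
            sum(!keep), " eigenvalue(s) below tolerance ",
            signif(tol, 3))
  Kmm_inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(Knm = Knm, Kmm = Kmm, Kmm_inv = Kmm_inv, inducing = ind,
       reconstruct = function() Knm %*% Kmm_inv %*% t(Knm))
}

#' Variance of the annual emission total
#'
#' `Var(total) = 1' Sigma_posterior 1` with `Sigma_posterior = K - K (K +
#' D)^-1 K`. With `method = "exact"` the dense matrices are used; with
#' `method = "nystrom"` the kernel is replaced by its low-rank factors and
#' the prior inverse is applied through the Woodbury identity, never
#' materializing an n x n matrix. The mean residual `mu_res` is reported
#' as a bias correction to the total (subtracted, since residuals are
#' prediction minus observation).
#'
#' @param cc per-pixel carbon combustion, g C m^-2 (burned pixels).
#' @param coords n x 2 pixel centers, meters.
#' @param sigma_cc residual sd per pixel, g C m^-2 (recycled).
#' @param mu_res mean residual, g C m^-2.
#' @param pixel_area m^2.
#' @param length_scale,cutoff_m kernel parameters.
#' @param method `"exact"` or `"nystrom"`.
#' @param m inducing points for the Nystrom path.
#' @return list with `total_g_c` (bias-corrected), `sd_g_c`, `var_g2`,
#'   and `total_pg_c` / `sd_pg_c`.
#' @export
annual_uncertainty <- function(cc, coords, sigma_cc, mu_res = 0,
                               pixel_area = 900, length_scale = 25000,
                               cutoff_m = length_scale,
                               method = c("exact", "nystrom"), m = 1000L) {
  method <- match.arg(method)
  n <- length(cc)
  if (n == 0L)
    return(list(total_g_c = 0, sd_g_c = 0, var_g2 = 0, total_pg_c = 0,
                sd_pg_c = 0))
  area <- rep_len(pixel_area, n)
  total <- sum((cc - mu_res) * area)
  w <- rep_len(sigma_cc, n) * area        # per-pixel emission sd, g C
  Dv <- w^2                               # heteroscedastic noise diagonal
  if (method == "exact") {
    cm <- covariance_matrices(coords, rep_len(sigma_cc, n), area,
                              length_scale, cutoff_m)
    # Var(total) = w' P w with P the unit-kernel posterior; the w-weights
    # carry the emission scale (sigma_CC,i * A_i) onto the correlations.
    v <- drop(crossprod(w, cm$k_posterior %*% w))
  } else {
    # v = w' Kt w - w' Kt (Kt + D)^-1 Kt w with Kt = C W^-1 C' (Nystrom),
    # the inverse applied through the Woodbury identity: only m x m solves
    # and n x m products, never an n x n matrix.
    m <- min(m, n)
    ny <- nystrom_approx(coords, m, length_scale, cutoff_m)
    C <- ny$Knm
    k1 <- C %*% (ny$Kmm_inv %*% crossprod(C, w))   # Kt w
    Dinv <- 1 / Dv
    B <- ny$Kmm + crossprod(C, C * Dinv)           # W + C' D^-1 C
    x <- Dinv * k1 - Dinv * (C %*% solve(B, crossprod(C, Dinv * k1)))
    v <- drop(crossprod(w, k1)) - drop(crossprod(k1, x))
  }
  v <- max(v, 0)
  list(total_g_c = total, sd_g_c = sqrt(v), var_g2 = v,
       total_pg_c = total / 1e15, sd_pg_c = sqrt(v) / 1e15)
}
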
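# Climate-anomaly computation, exponential climate-fire regressions, and
# Mann-Kendall trend testing.

#' Summer climate anomalies as z-scores against a long-term baseline
#'
#' Summer means (June-September by default, covering the early and late
#' fire season) are computed per year and variable from the monthly
#' table; z-scores use the mean and sd of the baseline summer means,
#' computed once per variable.
#'
#' @param monthly data.frame with `year`, `month` and one column per
#'   climate variable.
#' @param baseline_monthly same layout over the baseline period (>= 30
#'   years).
#' @param months months entering the summer mean (6:9).
#' @return list with `summer` (year x variable summer means), `z` (same
#'   shape, z-scores) and `baseline_stats` (mean, sd per variable).
#' @export
summer_anomalies <- function(monthly, baseline_monthly, months = 6:9) {
  vars <- setdiff(names(monthly), c("year", "month"))
  smean <- function(d) {
    d <- d[d$month %in% months, , drop = FALSE]
    out <- stats::aggregate(d[vars], by = list(year = d$year), FUN = mean)
    out[order(out$year), , drop = FALSE]
  }
  if (length(unique(baseline_monthly$year)) < 30L)
    stop("baseline must cover at least 30 years", call. = FALSE)
  base <- smean(baseline_monthly)
  study <- smean(monthly)
  stats_ <- data.frame(variable = vars,
                       mean = vapply(vars, function(v) mean(base[[v]]), 1),
                       sd = vapply(vars, function(v) stats::sd(base[[v]]), 1))
  if (any(stats_$sd == 0))
    stop("zero baseline standard deviation for: ",
         paste(stats_$variable[stats_$sd == 0], collapse = ", "),
         call. = FALSE)
  z <- study
  for (v in vars) z[[v]] <- (study[[v]] - stats_$mean[stats_$variable == v]) /
    stats_$sd[stats_$variable == v]
  list(summer = study, z = z, baseline_stats = stats_)
}

#' Exponential climate-fire regression
#'
#' Fits `log(BA) = a + b z` by ordinary least squares on the log scale
#' (the default; a log-link Gaussian GLM on the untransformed response is
#' also offered). Zero burned-area years are offset by half the smallest
#' positive annual value before the log transform.
#'
#' @param ba annual burned area (> 0 after the zero offset).
#' @param z climate anomaly z-scores, same length.
#' @param method `"log-ols"` or `"glm-log"`.
#' @return list with `a`, `b`, `r_squared` (log scale), `p_value`
#'   (two-sided, for b), `se_b`, `n`, and `zero_offset`.
#' @export
fit_exponential <- function(ba, z, method = c("log-ols", "glm-log")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(ba, z)
  ba <- ba[keep]; z <- z[keep]
  if (length(ba) < 4L) stop("need at least 4 years", call. = FALSE)
  offset <- 0
  if (any(ba <= 0)) {
    pos <- ba[ba > 0]
    if (length(pos) == 0L) stop("burned area is zero everywhere", call. = FALSE)
    offset <- min(pos) / 2
    ba <- ba + offset
  }
  if (method == "log-ols") {
    fit <- stats::lm(log(ba) ~ z)
    sm <- summary(fit)
    list(a = unname(stats::coef(fit)[1L]), b = unname(stats::coef(fit)[2L]),
         r_squared = sm$r.squared, p_value = sm$coefficients[2L, 4L],
         se_b = sm$coefficients[2L, 2L], n = length(ba),
         zero_offset = offset, method = method)
  } else {
    fit <- stats::glm(ba ~ z, family = stats::gaussian(link = "log"))
    sm <- summary(fit)
    ll <- log(ba)
    mu <- stats::predict(fit, type = "link")
    list(a = unname(stats::coef(fit)[1L]), b = unname(stats::coef(fit)[2L]),
         r_squared = 1 - sum((ll - mu)^2) / sum((ll - mean(ll))^2),
         p_value = sm$coefficients[2L, 4L],
         se_b = sm$coefficients[2L, 2L], n = length(ba),
         zero_offset = offset, method = method)
  }
}

#' Mann-Kendall trend test with Sen slope
#'
#' Standard S statistic over all pairs, tie-corrected variance, continuity
#' correction, two-sided normal p-value, and the Sen slope (median of
#' pairwise slopes). A constant series returns tau = 0, p = 1.
#'
#' @param x series values (time-ordered).
#' @param t optional time points (defaults to 1..n).
#' @return list with `S`, `tau`, `var_s`, `z`, `p_value`, `sen_slope`.
#' @export
mann_kendall <- function(x, t = seq_along(x)) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  dx <- outer(x, x, "-")
  dt <- outer(t, t, "-")
  up <- upper.tri(dx)
  S <- sum(sign(dx[up]) * sign(dt[up]))   # sign(dt) = +1 for ordered t
  ties <- table(x)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_s <= 0) {
    return(list(S = S, tau = 0, var_s = 0, z = 0, p_value = 1,
                sen_slope = 0))
  }
  z <- if (S > 0) (S - 1) / sqrt(var_s) else if (S < 0) (S + 1) / sqrt(var_s) else 0
  tau <- S / (0.5 * n * (n - 1))
  slopes <- (dx / dt)[up & dt != 0]
  list(S = S, tau = tau, var_s = var_s, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       sen_slope = stats::median(slopes))
}
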
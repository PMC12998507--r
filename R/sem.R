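# Piecewise structural equation modeling: per-node (mixed) regressions,
# standardized coefficients, marginal/conditional R2, d-separation basis
# set, and Fisher's C goodness test.

#' Specify a piecewise SEM
#'
#' The default graph encodes the climate-fire causal network used
#' throughout the package: climatic water deficit and minimum temperature
#' are exogenous; the Drought Code and PDSI are intermediate fire-weather
#' nodes fitted by simple linear regression; log total burned area, log
#' peat burned area, and belowground carbon combustion are endogenous
#' nodes fitted by linear mixed models with a random intercept per
#' geographic zone. Total and peat burned area share a correlated error
#' (their covariance is reported, not modeled causally), as do the two
#' drought proxies.
#'
#' @param paths two-column data.frame (`from`, `to`) of directed paths.
#' @param lmm_nodes responses fitted with a random group intercept.
#' @param group grouping factor name.
#' @param correlated_errors list of node pairs with free error covariance
#'   (removed from the d-separation basis set).
#' @return object of class `sem_spec`.
#' @export
sem_spec <- function(paths = NULL, lmm_nodes = NULL, group = "zone",
                     correlated_errors = NULL) {
  if (is.null(paths)) {
    paths <- data.frame(
      from = c("wd", "tmin", "wd", "dc", "pdsi", "dc", "pdsi",
               "log_peat_ba", "wd", "tmin"),
      to = c("dc", "dc", "pdsi", "log_ba", "log_ba", "log_peat_ba",
             "log_peat_ba", "bcc", "bcc", "bcc"))
    lmm_nodes <- c("log_ba", "log_peat_ba", "bcc")
    correlated_errors <- list(c("log_ba", "log_peat_ba"), c("dc", "pdsi"))
  }
  nodes <- unique(c(paths$from, paths$to))
  # acyclicity via Kahn's algorithm
  order <- character(0)
  remaining <- paths
  active <- nodes
  repeat {
    src <- setdiff(active, remaining$to)
    if (length(src) == 0L) break
    order <- c(order, src)
    remaining <- remaining[!(remaining$from %in% src), , drop = FALSE]
    active <- setdiff(active, src)
  }
  if (length(active) > 0L)
    stop("path specification is cyclic around: ",
         paste(active, collapse = ", "), call. = FALSE)
  structure(list(paths = paths, nodes = nodes, topo_order = order,
                 lmm_nodes = lmm_nodes %||% character(0), group = group,
                 correlated_errors = correlated_errors %||% list()),
            class = "sem_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parents_of <- function(spec, node) spec$paths$from[spec$paths$to == node]

# Missing-pairs d-separation basis set: every non-adjacent node pair,
# excluding exogenous-exogenous pairs and declared correlated errors;
# conditioning set = union of both nodes' parents.
basis_set <- function(spec) {
  nodes <- spec$topo_order
  exog <- setdiff(nodes, spec$paths$to)
  adj <- paste(pmin(spec$paths$from, spec$paths$to),
               pmax(spec$paths$from, spec$paths$to))
  ce <- vapply(spec$correlated_errors, function(p)
    paste(min(p), max(p)), character(1))
  out <- list()
  for (i in seq_along(nodes)) for (j in seq_len(i - 1L)) {
    a <- nodes[j]; b <- nodes[i]      # a earlier in topological order
    key <- paste(min(a, b), max(a, b))
    if (key %in% adj || key %in% ce) next
    if (a %in% exog && b %in% exog) next
    out[[length(out) + 1L]] <- list(
      x = a, y = b,                   # test x's coefficient in y's model
      cond = setdiff(union(parents_of(spec, a), parents_of(spec, b)),
                     c(a, b)))
  }
  out
}

fit_node <- function(response, predictors, data, spec) {
  use_lmm <- response %in% spec$lmm_nodes
  rhs <- if (length(predictors) == 0L) "1" else paste(predictors, collapse = " + ")
  if (use_lmm) {
    f <- stats::as.formula(paste(response, "~", rhs,
                                 "+ (1 |", spec$group, ")"))
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(f, data = data, REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) return(list(fit = fit, mixed = TRUE))
    warning("mixed model for ", response,
            " unidentifiable; falling back to ordinary regression")
  }
  f <- stats::as.formula(paste(response, "~", rhs))
  list(fit = stats::lm(f, data = data), mixed = FALSE)
}

coef_table <- function(fitobj, response) {
  sm <- summary(fitobj$fit)$coefficients
  keep <- setdiff(rownames(sm), "(Intercept)")
  if (length(keep) == 0L) return(NULL)
  pcol <- ncol(sm)   # lmerTest: Pr(>|t|) in col 5; lm: col 4
  data.frame(response = response, predictor = keep,
             beta = sm[keep, 1L], p_value = sm[keep, pcol],
             row.names = NULL)
}

r2_mixed <- function(fitobj, data, response) {
  if (!fitobj$mixed) {
    sm <- summary(fitobj$fit)
    return(c(marginal = sm$r.squared, conditional = sm$r.squared))
  }
  fit <- fitobj$fit
  var_f <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(v) v[1L], numeric(1)))
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Fisher's C over a set of independence-claim p-values
#'
#' C = -2 sum(log p); under the model, C ~ chi-square with 2k degrees of
#' freedom, k the number of claims.
#'
#' @param p_values claim p-values.
#' @return list with `C`, `df`, `p_value`.
#' @export
fisher_c <- function(p_values) {
  p <- pmax(p_values, .Machine$double.xmin)
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df,
       p_value = stats::pchisq(C, df, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' Every endogenous node is fitted by its family (linear mixed model with
#' a random group intercept, or ordinary regression); coefficients are
#' standardized by z-scaling all numeric variables with their grand
#' standard deviations beforehand. The d-separation basis set of missing
#' paths is tested by adding the independent variable to the dependent
#' node's model (conditioning on both nodes' parents) and Fisher's C
#' aggregates the claim p-values. The covariance between total and peat
#' burned area is reported both as a raw correlation and as the partial
#' (residual) correlation after their causal parents.
#'
#' @param data panel data.frame containing every node and the group column.
#' @param spec a [sem_spec()].
#' @return object of class `sem_fit`: `coefficients`, `r2`, `claims`,
#'   `fisher` (`C`, `df`, `p_value`), `cov_endogenous`, `singular_fits`.
#' @export
piecewise_sem <- function(data, spec = sem_spec()) {
  stopifnot(inherits(spec, "sem_spec"))
  miss <- setdiff(c(spec$nodes, spec$group), names(data))
  if (length(miss) > 0L)
    stop("missing variables: ", paste(miss, collapse = ", "), call. = FALSE)
  if (min(table(data[[spec$group]])) < 2L)
    stop("need at least 2 observations per group", call. = FALSE)
  sdata <- data
  for (v in spec$nodes) sdata[[v]] <- as.vector(scale(data[[v]]))

  endo <- unique(spec$paths$to)
  fits <- list(); coefs <- list(); r2 <- list(); singular <- character(0)
  for (node in intersect(spec$topo_order, endo)) {
    fo <- fit_node(node, parents_of(spec, node), sdata, spec)
    fits[[node]] <- fo
    coefs[[node]] <- coef_table(fo, node)
    r2[[node]] <- data.frame(response = node, t(r2_mixed(fo, sdata, node)))
    if (fo$mixed && lme4::isSingular(fo$fit)) singular <- c(singular, node)
  }

  claims <- basis_set(spec)
  claim_rows <- lapply(claims, function(cl) {
    fo <- fit_node(cl$y, c(cl$cond, cl$x), sdata, spec)
    ct <- coef_table(fo, cl$y)
    p <- ct$p_value[ct$predictor == cl$x]
    data.frame(independent = cl$x, dependent = cl$y,
               conditioning = paste(cl$cond, collapse = ", "),
               p_value = if (length(p) == 1L) p else NA_real_)
  })
  claim_df <- do.call(rbind, claim_rows)
  fc <- if (nrow(claim_df) > 0L) fisher_c(claim_df$p_value)
        else list(C = 0, df = 0L, p_value = 1)

  cov_endo <- NULL
  ce <- spec$correlated_errors
  if (length(ce) > 0L) {
    pair <- ce[[1L]]
    if (all(pair %in% names(fits))) {
      raw <- stats::cor(sdata[[pair[1L]]], sdata[[pair[2L]]])
      res <- function(nm) stats::residuals(fits[[nm]]$fit)
      partial <- stats::cor(res(pair[1L]), res(pair[2L]))
      cov_endo <- data.frame(a = pair[1L], b = pair[2L],
                             raw_correlation = raw,
                             partial_correlation = partial)
    }
  }
  structure(list(coefficients = do.call(rbind, coefs),
                 r2 = do.call(rbind, r2), claims = claim_df, fisher = fc,
                 cov_endogenous = cov_endo, singular_fits = singular,
                 spec = spec),
            class = "sem_fit")
}
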
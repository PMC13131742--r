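#' Per-individual derivative estimates with confidence intervals
#'
#' Evaluates a fitted causal-derivative estimate at arbitrary exposure
#' values: exactly for polynomial fits (TSLS, control function, PolyMR), via
#' the analytic spline derivative for NPIV (values outside the basis range
#' are clamped to it), and via the stratum LACE (with the stratum CI) for
#' stratification fits, where `x` must then be the evaluation sample the fit
#' was built on.
#'
#' @param fit An `nlmr_fit` or `nlmr_strat`.
#' @param x Exposure values at which to evaluate.
#' @return Tibble `x`, `estimate`, `conf_low`, `conf_high`.
#' @export
predict_derivative <- function(fit, x) {
  UseMethod("predict_derivative")
}

#' @export
predict_derivative.nlmr_fit <- function(fit, x) {
  gam_x <- fit$coefficients[fit$exposure_idx]
  Vx <- fit$vcov[fit$exposure_idx, fit$exposure_idx, drop = FALSE]
  out <- derivative_with_band(x, gam_x, Vx, fit$conf_level)
  out[c("x", "estimate", "conf_low", "conf_high")]
}

#' @export
predict_derivative.nlmr_npiv <- function(fit, x) {
  kx <- fit$diagnostics$knots_x
  deg <- fit$diagnostics$spline_degree
  Gd <- bspline_eval(kx, x, deg, deriv = 1)
  est <- drop(Gd %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((Gd %*% fit$vcov) * Gd), 0))
  zc <- qnorm(1 - (1 - fit$conf_level) / 2)
  tibble(x = x, estimate = est,
         conf_low = est - zc * se, conf_high = est + zc * se)
}

#' @export
predict_derivative.nlmr_strat <- function(fit, x) {
  if (length(x) != length(fit$assignment)) {
    abort("for stratified fits, `x` must be the evaluation sample the fit was built on (one value per individual)")
  }
  st <- fit$strata
  idx <- match(fit$assignment, st$stratum)
  tibble(x = x, estimate = st$estimate[idx],
         conf_low = st$conf_low[idx], conf_high = st$conf_high[idx])
}

#' Bias, MSE and coverage of the causal-derivative estimate
#'
#' Averages over the observed exposure values: bias is the mean of
#' \eqn{\hat d(x_i) - d(x_i)}, MSE the mean squared difference, and coverage
#' the fraction of observations whose confidence interval contains the true
#' derivative. Observations without a usable CI (e.g. weak strata) are
#' dropped from coverage, never counted as misses.
#'
#' @param fit An `nlmr_fit` or `nlmr_strat`.
#' @param x_obs Observed exposure values of the evaluation sample.
#' @param shape True causal shape label.
#' @param c1,c2 True causal coefficients.
#' @return One-row tibble `bias`, `mse`, `coverage`, `n_eval`.
#' @export
derivative_metrics <- function(fit, x_obs, shape, c1 = 0.05, c2 = 0.05) {
  truth <- true_derivative(shape, x_obs, c1, c2)
  pred <- predict_derivative(fit, x_obs)
  ok <- is.finite(pred$estimate)
  diff <- pred$estimate[ok] - truth[ok]
  has_ci <- ok & is.finite(pred$conf_low) & is.finite(pred$conf_high)
  coverage <- if (any(has_ci)) {
    mean(pred$conf_low[has_ci] <= truth[has_ci] &
           truth[has_ci] <= pred$conf_high[has_ci])
  } else {
    NA_real_
  }
  tibble(bias = mean(diff), mse = mean(diff^2), coverage = coverage,
         n_eval = sum(ok))
}

#' Empirical rejection rate with Wilson interval
#'
#' @param pvals Vector of p-values (NAs dropped with the denominator
#'   reported).
#' @param alpha Nominal level.
#' @param conf_level Confidence level of the Wilson interval.
#' @return One-row tibble `rate`, `n`, `conf_low`, `conf_high`.
#' @export
rejection_rate <- function(pvals, alpha = 0.05, conf_level = 0.95) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) abort("no p-values")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  k <- sum(pvals < alpha)
  n <- length(pvals)
  ci <- wilson_interval(k, n, conf_level)
  tibble(rate = k / n, n = n, conf_low = ci[["lower"]], conf_high = ci[["upper"]])
}

#' Residualize a variable on covariates
#'
#' OLS residuals (intercept always included), used to strip covariates from
#' exposure and outcome for the estimators that cannot carry them directly.
#' Collinear covariate columns are dropped with a warning.
#'
#' @param v Numeric vector.
#' @param covariates Numeric matrix or data frame of covariates.
#' @return Residual vector (mean zero).
#' @export
residualize_covariates <- function(v, covariates) {
  C <- as.matrix(covariates)
  storage.mode(C) <- "double"
  q <- qr(cbind(1, C))
  if (q$rank < ncol(C) + 1L) {
    dropped <- q$pivot[seq(q$rank + 1L, ncol(C) + 1L)] - 1L
    nm <- colnames(C)[dropped] %||% paste0("V", dropped)
    warn(paste0("dropping collinear covariate column(s): ",
                paste(nm, collapse = ", ")),
         class = "nlmrhet_collinear_dropped")
    keep <- setdiff(seq_len(ncol(C)), dropped)
    q <- qr(cbind(1, C[, keep, drop = FALSE]))
  }
  drop(qr.resid(q, v))
}
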
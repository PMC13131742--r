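new_causal_fit <- function(method, coefficients, vcov, exposure_idx,
                           degree, grid, conf_level, p_overall, p_nonlinear,
                           diagnostics = list(), extra = list()) {
  structure(
    c(list(method = method,
           coefficients = coefficients,
           vcov = vcov,
           exposure_idx = exposure_idx,
           degree = degree,
           grid = grid,
           conf_level = conf_level,
           p_overall = p_overall,
           p_nonlinear = p_nonlinear,
           diagnostics = diagnostics),
      extra),
    class = c(paste0("nlmr_", method), "nlmr_fit")
  )
}

# Derivative of a raw-polynomial fit and its delta-method covariance factors.
poly_derivative_basis <- function(x, degree) {
  out <- vapply(seq_len(degree), function(j) j * x^(j - 1), numeric(length(x)))
  matrix(out, ncol = degree)
}

derivative_with_band <- function(x, gamma, vg, conf_level, crit = NULL) {
  degree <- length(gamma)
  B <- poly_derivative_basis(x, degree)
  est <- drop(B %*% gamma)
  se <- sqrt(pmax(rowSums((B %*% vg) * B), 0))
  z <- crit %||% qnorm(1 - (1 - conf_level) / 2)
  tibble(x = x, estimate = est, se = se,
         conf_low = est - z * se, conf_high = est + z * se)
}

exposure_grid <- function(x, grid_size = 101) {
  qs <- quantile(x, c(0.01, 0.99), names = FALSE)
  seq(qs[1], qs[2], length.out = grid_size)
}

#' Polynomial two-stage least squares
#'
#' Fits the nonlinear IV model by regressing each exposure power
#' \eqn{X^j, j = 1..degree} on an instrument polynomial basis (powers of Z up
#' to `max(instrument_degree, degree)`) in the first stage, and the outcome on
#' the fitted values in the second. With a single scalar instrument the
#' instrument basis must be at least as rich as the outcome basis so that
#' every exposure power is separately instrumented. Coefficient covariance is
#' the joint two-stage (2SLS) heteroskedasticity-robust sandwich, using
#' second-stage residuals computed from the *original* regressors — never the
#' naive OLS covariance of stage two. The causal derivative
#' \eqn{\hat d(x) = \sum_j j \hat\gamma_j x^{j-1}} gets delta-method pointwise
#' bands.
#'
#' @param data Data frame with exposure, outcome and instrument columns.
#' @param degree Polynomial degree of the outcome (exposure) basis.
#' @param instrument_degree Optional instrument-basis degree; defaults to
#'   `degree` and is raised to `degree` if smaller.
#' @param covariates Optional character vector of covariate columns, included
#'   in both stages.
#' @param exposure,outcome,instrument Column names (defaults `"x"`, `"y"`,
#'   `"z"`).
#' @param conf_level Confidence level for derivative bands.
#' @param grid_size Number of grid points (1st to 99th exposure percentile)
#'   for the reported derivative curve.
#' @return An object of classes `nlmr_tsls`, `nlmr_fit`; see [tidy.nlmr_fit()]
#'   and [glance.nlmr_fit()].
#' @examples
#' set.seed(1)
#' d <- data.frame(z = rnorm(2000), u = rnorm(2000))
#' d$x <- 0.5 * d$z + d$u + rnorm(2000)
#' d$y <- 0.2 * d$x - d$u + rnorm(2000)
#' fit <- fit_polynomial_tsls(d, degree = 1)
#' tidy(fit)
#' @export
fit_polynomial_tsls <- function(data, degree = 2, instrument_degree = NULL,
                                covariates = NULL,
                                exposure = "x", outcome = "y", instrument = "z",
                                conf_level = 0.95, grid_size = 101) {
  stopifnot(degree >= 1)
  x <- col_vec(data, exposure)
  y <- col_vec(data, outcome)
  z <- col_vec(data, instrument)
  if (sd(x) == 0) abort("exposure is constant")
  if (sd(z) == 0) abort("instrument is constant")
  C <- covariate_matrix(data, covariates)
  K <- max(instrument_degree %||% degree, degree)
  W <- cbind(`(Intercept)` = 1, poly_raw(z, K, "z"), C)
  R <- cbind(`(Intercept)` = 1, poly_raw(x, degree, "x"), C)
  qw <- qr(W)
  Rhat <- qr.fitted(qw, R)
  colnames(Rhat) <- colnames(R)
  qr2 <- qr(Rhat)
  if (qr2$rank < ncol(Rhat)) {
    abort("stage-one fitted-value matrix is rank deficient; reduce the degree",
          class = "nlmrhet_rank")
  }
  gamma <- qr.coef(qr2, y)
  e <- drop(y - R %*% gamma)          # structural residuals (original regressors)
  A <- solve(crossprod(Rhat))         # (Rhat'Rhat)^{-1}
  meat <- crossprod(Rhat * e)
  V <- A %*% meat %*% A
  dimnames(V) <- list(colnames(R), colnames(R))
  kappa_rhat <- kappa(Rhat, exact = FALSE)
  collinear <- is.finite(kappa_rhat) && kappa_rhat > 1e8
  if (collinear) {
    warn("stage-one predictions are nearly collinear; estimates may be unstable",
         class = "nlmrhet_collinearity_warning")
  }
  exposure_idx <- 1 + seq_len(degree)
  gam_x <- gamma[exposure_idx]
  Vx <- V[exposure_idx, exposure_idx, drop = FALSE]
  p_overall <- wald_pvalue(gam_x, Vx)
  p_nonlinear <- if (degree >= 2) {
    wald_pvalue(gam_x[-1], Vx[-1, -1, drop = FALSE])
  } else {
    NA_real_
  }
  grid <- derivative_with_band(exposure_grid(x, grid_size), gam_x, Vx, conf_level)
  new_causal_fit(
    "tsls", gamma, V, exposure_idx, degree, grid, conf_level,
    p_overall, p_nonlinear,
    diagnostics = list(condition_number = kappa_rhat, collinear = collinear,
                       instrument_degree = K, n = length(y),
                       rss = sum((y - drop(Rhat %*% gamma))^2))
  )
}

wald_pvalue <- function(b, V, df = length(b)) {
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) {
    warn("singular coefficient covariance; using pseudo-inverse",
         class = "nlmrhet_singular_vcov")
    s <- svd(V)
    pos <- s$d > max(s$d) * 1e-12
    Vi <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    df <- sum(pos)
  }
  stat <- drop(t(b) %*% Vi %*% b)
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Overall-effect Wald test of a polynomial fit
#'
#' Tests that all exposure-term coefficients are zero, against a chi-squared
#' reference with as many degrees of freedom as exposure terms.
#'
#' @param fit An `nlmr_fit` with coefficients and covariance.
#' @return A one-row tibble: `statistic` implied by `p_value`, `df`,
#'   `p_value`.
#' @export
wald_overall_test <- function(fit) {
  stopifnot(inherits(fit, "nlmr_fit"))
  idx <- fit$exposure_idx
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  p <- wald_pvalue(b, V)
  tibble(df = length(b), p_value = p)
}

#' Nonlinearity Wald test of a polynomial fit
#'
#' Tests that all exposure-term coefficients of degree two or higher are
#' zero. For a degree-1 fit the test is not applicable and `p_value` is `NA`.
#'
#' @inheritParams wald_overall_test
#' @return A one-row tibble: `df`, `p_value`, `applicable`.
#' @export
wald_nonlinearity_test <- function(fit) {
  stopifnot(inherits(fit, "nlmr_fit"))
  if (fit$degree < 2) {
    return(tibble(df = 0L, p_value = NA_real_, applicable = FALSE))
  }
  idx <- fit$exposure_idx[-1]
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  tibble(df = length(b), p_value = wald_pvalue(b, V), applicable = TRUE)
}

#' Polynomial TSLS with AIC degree selection
#'
#' Fits TSLS at every degree from 1 to `max_degree` and returns the
#' AIC-minimizing fit. The AIC is computed from the second-stage Gaussian
#' likelihood, \eqn{n \log(RSS/n) + 2(k + 1)} with RSS the second-stage
#' residual sum of squares and k the number of regression parameters.
#' Degrees failing to fit (rank deficiency) are skipped.
#'
#' @inheritParams fit_polynomial_tsls
#' @param max_degree Largest degree considered.
#' @return The selected `nlmr_fit`, with an `aic_path` tibble and
#'   `selected_degree` attached.
#' @export
select_degree_aic <- function(data, max_degree = 10, covariates = NULL,
                              exposure = "x", outcome = "y", instrument = "z",
                              conf_level = 0.95, grid_size = 101) {
  stopifnot(max_degree >= 1)
  y <- col_vec(data, outcome)
  n <- length(y)
  fits <- vector("list", max_degree)
  aics <- rep(NA_real_, max_degree)
  for (d in seq_len(max_degree)) {
    fit <- tryCatch(
      suppressWarnings(fit_polynomial_tsls(
        data, degree = d, covariates = covariates, exposure = exposure,
        outcome = outcome, instrument = instrument,
        conf_level = conf_level, grid_size = grid_size)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$diagnostics$rss
    k <- length(fit$coefficients)
    aics[d] <- n * log(rss / n) + 2 * (k + 1)
    fits[[d]] <- fit
  }
  if (all(is.na(aics))) abort("no polynomial degree could be fitted")
  best <- which.min(aics)
  fit <- fits[[best]]
  fit$selected_degree <- best
  fit$aic_path <- tibble(degree = seq_len(max_degree), aic = aics)
  fit
}
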
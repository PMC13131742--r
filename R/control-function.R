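# Shared machinery for control-function fits: stage one regresses X on the
# instrument basis, stage two regresses Y on exposure powers plus powers of
# the stage-one residual (the control terms). Identification relies on the
# first-stage model capturing ALL dependence of X on Z; instrument-exposure
# effect heterogeneity breaks exactly that, which is why these estimators are
# biased under directional interaction effects.
cf_design <- function(x, y, z, C, degree, residual_degree, instrument_degree) {
  W <- cbind(1, poly_raw(z, instrument_degree, "z"), C)
  ehat <- drop(qr.resid(qr(W), x))
  R <- cbind(`(Intercept)` = 1, poly_raw(x, degree, "x"),
             poly_raw(ehat, residual_degree, "e"), C)
  list(R = R, ehat = ehat)
}

cf_solve <- function(R, y) {
  q <- qr(R)
  if (q$rank < ncol(R)) {
    abort("control-function design is rank deficient", class = "nlmrhet_rank")
  }
  qr.coef(q, y)
}

#' Control-function nonlinear IV estimator
#'
#' Stage one regresses the exposure on the instrument basis (linear by
#' default, following the PolyMR convention) and keeps the residuals
#' \eqn{\hat\epsilon}; stage two regresses the outcome on exposure powers up
#' to `degree`, residual powers up to `residual_degree` (the control terms),
#' and any covariates. Exposure-term coefficients are the causal parameters.
#' `residual_degree > 1` gives the PolyMR-style extension with higher-order
#' control terms.
#'
#' Because the control term is a generated regressor, naive OLS second-stage
#' variances are not honest; the default standard errors come from a
#' nonparametric pairs bootstrap over both stages (`se = "bootstrap"`,
#' `n_boot` resamples). `se = "asymptotic"` gives the plain second-stage OLS
#' (HC0) covariance, matching common base-R implementations, and is much
#' faster.
#'
#' @inheritParams fit_polynomial_tsls
#' @param residual_degree Highest power of the first-stage residual included
#'   as a control term.
#' @param instrument_degree First-stage instrument polynomial degree
#'   (default 1: linear first stage).
#' @param se `"bootstrap"` (default) or `"asymptotic"`.
#' @param n_boot Bootstrap resamples.
#' @return Classes `nlmr_cf`, `nlmr_fit`.
#' @export
fit_control_function <- function(data, degree = 2, residual_degree = 1,
                                 instrument_degree = 1, covariates = NULL,
                                 exposure = "x", outcome = "y", instrument = "z",
                                 se = c("bootstrap", "asymptotic"),
                                 n_boot = 500,
                                 conf_level = 0.95, grid_size = 101) {
  se <- match.arg(se)
  stopifnot(degree >= 1, residual_degree >= 1)
  x <- col_vec(data, exposure)
  y <- col_vec(data, outcome)
  z <- col_vec(data, instrument)
  if (sd(x) == 0) abort("exposure is constant")
  if (sd(z) == 0) abort("instrument is constant")
  C <- covariate_matrix(data, covariates)
  des <- cf_design(x, y, z, C, degree, residual_degree, instrument_degree)
  gamma <- cf_solve(des$R, y)
  n <- length(y)
  p <- length(gamma)
  exposure_idx <- 1 + seq_len(degree)

  if (se == "bootstrap") {
    # normal equations in the resampling loop: the designs here are small
    # (p <= a dozen columns) and well conditioned, and this is ~20x faster
    # than refitting by QR at biobank-scale n
    boot_fit <- function(idx) {
      zi <- z[idx]; xi <- x[idx]; yi <- y[idx]
      Ci <- if (is.null(C)) NULL else C[idx, , drop = FALSE]
      W <- cbind(1, poly_raw(zi, instrument_degree, "z"), Ci)
      eh <- xi - drop(W %*% solve(crossprod(W), crossprod(W, xi)))
      R <- cbind(1, poly_raw(xi, degree, "x"),
                 poly_raw(eh, residual_degree, "e"), Ci)
      drop(solve(crossprod(R), crossprod(R, yi)))
    }
    boot_gamma <- matrix(NA_real_, n_boot, p)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      g <- tryCatch(boot_fit(idx), error = function(e) NULL)
      if (!is.null(g)) boot_gamma[b, ] <- g
    }
    ok <- complete.cases(boot_gamma)
    if (sum(ok) < max(20, p + 2)) abort("too few successful bootstrap resamples")
    V <- stats::cov(boot_gamma[ok, , drop = FALSE])
  } else {
    e <- drop(y - des$R %*% gamma)
    A <- solve(crossprod(des$R))
    V <- A %*% crossprod(des$R * e) %*% A
  }
  dimnames(V) <- list(names(gamma), names(gamma))

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
    "cf", gamma, V, exposure_idx, degree, grid, conf_level,
    p_overall, p_nonlinear,
    diagnostics = list(residual_degree = residual_degree,
                       instrument_degree = instrument_degree,
                       se = se, n = n,
                       rss = sum((y - drop(des$R %*% gamma))^2))
  )
}

# Gaussian likelihood-ratio statistic for nested least-squares fits.
lrt_pvalue <- function(rss_null, rss_full, n, df) {
  if (df <= 0) return(NA_real_)
  stat <- n * log(rss_null / rss_full)
  pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' PolyMR-style control-function estimator with likelihood-ratio tests
#'
#' Control-function fit with exposure and residual polynomials up to
#' `max_degree`. With `model_selection = TRUE`, exposure terms are backward
#' eliminated — the least significant exposure term (largest p-value) is
#' dropped until all retained exposure terms have p < `alpha_select`; control
#' (residual) terms are never dropped. The overall-effect p-value is a
#' likelihood-ratio test against the model with control terms only; the
#' nonlinearity p-value compares the retained nonlinear exposure terms
#' against the model with a linear exposure term plus controls. Selection is
#' not accounted for in the tests, which is precisely why selection inflates
#' type I error.
#'
#' @inheritParams fit_control_function
#' @param max_degree Polynomial degree of both exposure and control terms.
#' @param model_selection Backward-eliminate exposure terms?
#' @param alpha_select Retention threshold for selection.
#' @return Classes `nlmr_polymr`, `nlmr_fit`. Exposure-term
#'   coefficients of eliminated terms are zero; `retained` lists the kept
#'   exposure degrees.
#' @export
fit_polymr <- function(data, max_degree = 10, model_selection = FALSE,
                       covariates = NULL,
                       exposure = "x", outcome = "y", instrument = "z",
                       alpha_select = 0.05,
                       conf_level = 0.95, grid_size = 101) {
  stopifnot(max_degree >= 1)
  x <- col_vec(data, exposure)
  y <- col_vec(data, outcome)
  z <- col_vec(data, instrument)
  if (sd(x) == 0) abort("exposure is constant")
  if (sd(z) == 0) abort("instrument is constant")
  C <- covariate_matrix(data, covariates)
  n <- length(y)

  W <- cbind(1, z, C)
  ehat <- drop(qr.resid(qr(W), x))
  Xpow <- poly_raw(x, max_degree, "x")
  Epow <- poly_raw(ehat, max_degree, "e")
  base_cols <- cbind(`(Intercept)` = 1, Epow, C)   # control-only model

  fit_ls <- function(extra) {
    R <- cbind(base_cols, extra)
    q <- qr(R)
    gamma <- qr.coef(q, y)
    res <- drop(qr.resid(q, y))
    list(R = R, gamma = gamma, rss = sum(res^2), qr = q, res = res)
  }

  retained <- seq_len(max_degree)
  repeat {
    f <- fit_ls(Xpow[, retained, drop = FALSE])
    if (!model_selection || length(retained) == 0) break
    # t-test p-values of exposure terms from the OLS fit
    sigma2 <- f$rss / (n - f$qr$rank)
    A <- tryCatch(solve(crossprod(f$R)), error = function(e) NULL)
    if (is.null(A)) break
    se_all <- sqrt(pmax(diag(A), 0) * sigma2)
    idx <- ncol(base_cols) + seq_along(retained)
    pvals <- 2 * pnorm(-abs(f$gamma[idx] / se_all[idx]))
    if (all(pvals < alpha_select, na.rm = TRUE)) break
    retained <- retained[-which.max(pvals)]
    if (length(retained) == 0) {
      f <- fit_ls(NULL)
      break
    }
  }

  rss_full <- f$rss
  rss_ctrl <- fit_ls(NULL)$rss
  rss_lin <- fit_ls(Xpow[, 1, drop = FALSE])$rss
  nonlin_retained <- setdiff(retained, 1L)
  p_overall <- lrt_pvalue(rss_ctrl, rss_full, n, df = max(length(retained), 1))
  p_nonlinear <- lrt_pvalue(rss_lin, min(rss_full, rss_lin), n,
                            df = max(length(nonlin_retained), 1))

  # Full-length exposure coefficient vector (zeros for eliminated terms) and
  # its naive OLS covariance; PolyMR-style inference is LRT-based, the
  # covariance is only used for derivative bands.
  gamma_x <- rep(0, max_degree)
  names(gamma_x) <- paste0("x", seq_len(max_degree))
  Vx <- matrix(0, max_degree, max_degree, dimnames = list(names(gamma_x), names(gamma_x)))
  if (length(retained) > 0) {
    idx <- ncol(base_cols) + seq_along(retained)
    gamma_x[retained] <- f$gamma[idx]
    sigma2 <- rss_full / (n - f$qr$rank)
    A <- solve(crossprod(f$R))
    Vx[retained, retained] <- A[idx, idx, drop = FALSE] * sigma2
  }
  grid <- derivative_with_band(exposure_grid(x, grid_size), gamma_x, Vx, conf_level)
  coefs <- c(`(Intercept)` = unname(f$gamma[1]), gamma_x)
  Vfull <- rbind(0, cbind(0, Vx))
  dimnames(Vfull) <- list(names(coefs), names(coefs))
  new_causal_fit(
    "polymr", coefs, Vfull, exposure_idx = 1 + seq_len(max_degree),
    degree = max_degree, grid, conf_level, p_overall, p_nonlinear,
    diagnostics = list(model_selection = model_selection,
                       retained = retained, n = n,
                       rss = rss_full),
    extra = list(retained = retained)
  )
}
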
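# Equal-as-possible partition of n ordered items into Q blocks: the first
# n %% Q blocks get one extra member, so counts differ by at most one.
block_sizes <- function(n, Q) {
  sizes <- rep(n %/% Q, Q)
  r <- n %% Q
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  sizes
}

#' Residual stratification
#'
#' Regresses the exposure on the instrument (plus covariates) linearly and
#' assigns individuals to quantile bins of the residual. Stratifying on the
#' residual rather than the exposure itself avoids collider bias — but is
#' only valid when the residual is independent of the instrument, which
#' instrument-exposure effect heterogeneity breaks. Ties are broken by stable
#' order of appearance.
#'
#' @param data Data frame with exposure and instrument columns.
#' @param n_strata Number of strata (at least 2).
#' @param covariates Optional covariate column names for the residual
#'   regression.
#' @param exposure,instrument Column names.
#' @return The input data as a tibble with added columns `.resid` and
#'   `.stratum` (integer, 1 = lowest residuals).
#' @export
residual_stratify <- function(data, n_strata = 10, covariates = NULL,
                              exposure = "x", instrument = "z") {
  if (n_strata < 2) abort("n_strata must be at least 2")
  x <- col_vec(data, exposure)
  z <- col_vec(data, instrument)
  n <- length(x)
  if (n < n_strata) abort("fewer individuals than strata")
  C <- covariate_matrix(data, covariates)
  W <- cbind(1, z, C)
  r <- drop(qr.resid(qr(W), x))
  if (sd(r) < .Machine$double.eps * max(1, sd(x))) {
    warn("exposure residuals are (numerically) constant; stratification is degenerate",
         class = "nlmrhet_degenerate_strata")
  }
  ord <- order(r)                           # stable for ties
  stratum <- integer(n)
  stratum[ord] <- rep(seq_len(n_strata), times = block_sizes(n, n_strata))
  out <- tibble::as_tibble(data)
  out$.resid <- r
  out$.stratum <- stratum
  out
}

#' Doubly-ranked stratification
#'
#' Ranks individuals by the instrument, forms consecutive pre-strata of size
#' `n_strata`, ranks within each pre-stratum by exposure, and sends the q-th
#' exposure-ranked member of every pre-stratum to stratum q. Valid under the
#' rank-preservation assumption that exposure ranks given the instrument do
#' not depend on the instrument value; heterogeneous instrument effects can
#' violate it. When n is not a multiple of `n_strata`, the last pre-stratum
#' absorbs the remainder and stratum indices within it are assigned by
#' interpolated rank. Ties broken by stable order of appearance.
#'
#' @inheritParams residual_stratify
#' @return The input data as a tibble with added columns `.prestratum` and
#'   `.stratum`.
#' @export
doubly_ranked_stratify <- function(data, n_strata = 10,
                                   exposure = "x", instrument = "z") {
  if (n_strata < 2) abort("n_strata must be at least 2")
  x <- col_vec(data, exposure)
  z <- col_vec(data, instrument)
  n <- length(x)
  if (n < n_strata) abort("fewer individuals than strata")
  Q <- as.integer(n_strata)
  n_pre <- n %/% Q                      # pre-strata of size Q; last absorbs rest
  ord_z <- order(z)
  pre <- integer(n)
  pre_sizes <- rep(Q, n_pre)
  pre_sizes[n_pre] <- pre_sizes[n_pre] + n %% Q
  pre[ord_z] <- rep(seq_len(n_pre), times = pre_sizes)
  stratum <- integer(n)
  for (p in seq_len(n_pre)) {
    members <- which(pre == p)
    rk <- rank(x[members], ties.method = "first")
    size <- length(members)
    stratum[members] <- if (size == Q) rk else ceiling(rk * Q / size)
  }
  out <- tibble::as_tibble(data)
  out$.prestratum <- pre
  out$.stratum <- stratum
  out
}

#' Per-stratum IV (Wald-ratio) estimates
#'
#' Within each stratum computes the localized average causal effect (LACE) as
#' the ratio estimate \eqn{\widehat{Cov}(Y,Z)/\widehat{Cov}(X,Z)} with the
#' standard linear-IV (delta-method) standard error, plus three tests:
#' the Cauchy-combined overall test, the quadratic nonlinearity test
#' (inverse-variance-weighted meta-regression of LACE on stratum mean
#' exposure) and Cochran's Q. Strata whose exposure-instrument covariance is
#' numerically zero are flagged weak and excluded from the tests.
#'
#' @param data A stratified tibble from [residual_stratify()] or
#'   [doubly_ranked_stratify()] (must contain `.stratum`).
#' @param covariates Optional covariate columns, adjusted for within each
#'   stratum in both regressions.
#' @param exposure,outcome,instrument Column names.
#' @param method_tag Label stored on the fit.
#' @param conf_level Confidence level for per-stratum intervals.
#' @return An object of class `nlmr_strat` with a `strata` tibble
#'   (stratum, n, mean_x, estimate, se, statistic, p_value, conf_low,
#'   conf_high, weak), per-individual `assignment`, `p_overall`,
#'   `p_nonlinear_quad`, `p_nonlinear_q`.
#' @export
stratum_iv_estimates <- function(data, covariates = NULL,
                                 exposure = "x", outcome = "y",
                                 instrument = "z",
                                 method_tag = "stratified",
                                 conf_level = 0.95) {
  if (!".stratum" %in% names(data)) abort("data must carry a `.stratum` column")
  x <- col_vec(data, exposure)
  y <- col_vec(data, outcome)
  z <- col_vec(data, instrument)
  C <- covariate_matrix(data, covariates)
  s <- data$.stratum
  strata_ids <- sort(unique(s))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  rows <- purrr::map(strata_ids, function(q) {
    i <- which(s == q)
    xi <- x[i]; yi <- y[i]; zi <- z[i]
    if (!is.null(C)) {
      Ci <- C[i, , drop = FALSE]
      xi <- residualize_covariates(xi, Ci)
      yi <- residualize_covariates(yi, Ci)
      zi <- residualize_covariates(zi, Ci)
    }
    nq <- length(i)
    sxz <- cov(xi, zi); syz <- cov(yi, zi); szz <- var(zi)
    weak <- !is.finite(sxz) || abs(sxz) < 1e-10 * sd(x) * sd(z)
    if (weak) {
      return(tibble(stratum = q, n = nq, mean_x = mean(x[i]),
                    estimate = NA_real_, se = NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    conf_low = NA_real_, conf_high = NA_real_, weak = TRUE))
    }
    b <- syz / sxz
    e <- (yi - mean(yi)) - b * (xi - mean(xi))
    se <- sqrt(sum(e^2) / (nq - 2) * szz * (nq - 1)) / abs(sxz * (nq - 1))
    stat <- b / se
    tibble(stratum = q, n = nq, mean_x = mean(x[i]),
           estimate = b, se = se, statistic = stat,
           p_value = 2 * pnorm(-abs(stat)),
           conf_low = b - zc * se, conf_high = b + zc * se, weak = FALSE)
  })
  strata <- dplyr::bind_rows(rows)
  if (any(strata$weak)) {
    warn(sprintf("%d stratum/strata flagged weak (near-zero exposure-instrument covariance) and excluded from tests",
                 sum(strata$weak)), class = "nlmrhet_weak_stratum")
  }
  fit <- structure(
    list(method = method_tag,
         strata = strata,
         assignment = s,
         conf_level = conf_level,
         p_overall = NA_real_,
         p_nonlinear_quad = NA_real_,
         p_nonlinear_q = NA_real_),
    class = "nlmr_strat"
  )
  ok <- !strata$weak
  if (any(ok)) {
    fit$p_overall <- cauchy_combine(strata$p_value[ok])
  }
  fit$p_nonlinear_quad <- quadratic_test(fit)$p_value
  fit$p_nonlinear_q <- cochran_q_test(fit)$p_value
  fit
}

#' @export
print.nlmr_strat <- function(x, ...) {
  cat(sprintf("<nlmr_strat: %s> %d strata\n", x$method, nrow(x$strata)))
  print(x$strata)
  cat(sprintf("p_overall (Cauchy) = %.3g, p_quadratic = %.3g, p_CochranQ = %.3g\n",
              x$p_overall, x$p_nonlinear_quad, x$p_nonlinear_q))
  invisible(x)
}

#' Quadratic nonlinearity test on stratum estimates
#'
#' Inverse-variance-weighted (fixed-effect) meta-regression of the stratum
#' LACE estimates on stratum mean exposure; the p-value for the slope tests
#' the null that the causal derivative is constant in the exposure.
#'
#' @param fit An `nlmr_strat` fit.
#' @return One-row tibble `slope`, `se`, `p_value`, `applicable` (needs at
#'   least 3 usable strata).
#' @export
quadratic_test <- function(fit) {
  stopifnot(inherits(fit, "nlmr_strat"))
  st <- fit$strata[!fit$strata$weak, ]
  if (nrow(st) < 3) {
    return(tibble(slope = NA_real_, se = NA_real_, p_value = NA_real_,
                  applicable = FALSE))
  }
  w <- 1 / st$se^2
  X <- cbind(1, st$mean_x)
  XtWX <- crossprod(X * sqrt(w))
  coefs <- solve(XtWX, crossprod(X, w * st$estimate))
  V <- solve(XtWX)                    # known-variance (fixed-effect) weights
  slope <- coefs[2]
  se <- sqrt(V[2, 2])
  tibble(slope = slope, se = se,
         p_value = 2 * pnorm(-abs(slope / se)), applicable = TRUE)
}

#' Cochran's Q heterogeneity test on stratum estimates
#'
#' \eqn{Q = \sum_q (\hat\beta_q - \hat\beta_{IVW})^2 / se_q^2} against a
#' chi-squared with (number of usable strata - 1) degrees of freedom, where
#' \eqn{\hat\beta_{IVW}} is the inverse-variance-weighted mean. Rejection
#' indicates the stratum effects are not all equal, i.e. a nonlinear (or
#' otherwise non-constant) causal derivative.
#'
#' @param fit An `nlmr_strat` fit.
#' @return One-row tibble `q`, `df`, `p_value`, `applicable`.
#' @export
cochran_q_test <- function(fit) {
  stopifnot(inherits(fit, "nlmr_strat"))
  st <- fit$strata[!fit$strata$weak, ]
  if (nrow(st) < 2) {
    return(tibble(q = NA_real_, df = NA_integer_, p_value = NA_real_,
                  applicable = FALSE))
  }
  w <- 1 / st$se^2
  b_ivw <- sum(w * st$estimate) / sum(w)
  q <- sum(w * (st$estimate - b_ivw)^2)
  df <- nrow(st) - 1L
  tibble(q = q, df = df, p_value = pchisq(q, df, lower.tail = FALSE),
         applicable = TRUE)
}

#' Cauchy combination (ACAT) of p-values
#'
#' Combines p-values via \eqn{T = \sum_q w_q \tan\{(0.5 - p_q)\pi\} /
#' \sum_q w_q} and \eqn{p = 0.5 - \arctan(T)/\pi}. Valid under arbitrary
#' dependence between the component tests. P-values numerically at 0 or 1
#' are clipped to machine-safe bounds with a warning.
#'
#' @param pvals Vector of p-values in (0, 1).
#' @param weights Optional nonnegative weights (default equal).
#' @return Combined p-value (scalar).
#' @examples
#' cauchy_combine(c(0.01, 0.5, 0.9))
#' @export
cauchy_combine <- function(pvals, weights = NULL) {
  if (length(pvals) == 0) abort("no p-values to combine")
  if (any(!is.finite(pvals))) abort("p-values must be finite")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  weights <- weights %||% rep(1, length(pvals))
  if (length(weights) != length(pvals) || any(weights < 0)) {
    abort("weights must be nonnegative and match the p-values in length")
  }
  eps <- 1e-15
  if (any(pvals < eps | pvals > 1 - eps)) {
    warn("p-values at 0 or 1 clipped for the Cauchy combination",
         class = "nlmrhet_pvalue_clip")
    pvals <- pmin(pmax(pvals, eps), 1 - eps)
  }
  t_stat <- sum(weights * tan((0.5 - pvals) * pi)) / sum(weights)
  0.5 - atan(t_stat) / pi
}

#' Residual- or doubly-ranked-stratification nonlinear MR in one call
#'
#' Convenience wrappers: stratify, estimate per-stratum LACEs, and run the
#' overall (Cauchy) and nonlinearity (quadratic, Cochran's Q) tests.
#'
#' @inheritParams residual_stratify
#' @inheritParams stratum_iv_estimates
#' @param outcome Outcome column name.
#' @return An `nlmr_strat` fit.
#' @export
fit_residual_stratification <- function(data, n_strata = 10, covariates = NULL,
                                        exposure = "x", outcome = "y",
                                        instrument = "z", conf_level = 0.95) {
  strat <- residual_stratify(data, n_strata, covariates, exposure, instrument)
  stratum_iv_estimates(strat, covariates, exposure, outcome, instrument,
                       method_tag = "residual_stratification", conf_level)
}

#' @rdname fit_residual_stratification
#' @export
fit_doubly_ranked <- function(data, n_strata = 10, covariates = NULL,
                              exposure = "x", outcome = "y",
                              instrument = "z", conf_level = 0.95) {
  strat <- doubly_ranked_stratify(data, n_strata, exposure, instrument)
  stratum_iv_estimates(strat, covariates, exposure, outcome, instrument,
                       method_tag = "doubly_ranked_stratification", conf_level)
}
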
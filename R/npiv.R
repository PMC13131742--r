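# B-spline design helpers built on splines::splineDesign so that value and
# derivative bases share one knot sequence. The basis includes the partition
# of unity, i.e. spans constants.
bspline_knots <- function(v, n_interior, degree) {
  boundary <- range(v)
  interior <- if (n_interior > 0) {
    unique(quantile(v, (seq_len(n_interior)) / (n_interior + 1), names = FALSE))
  } else {
    numeric(0)
  }
  interior <- interior[interior > boundary[1] & interior < boundary[2]]
  c(rep(boundary[1], degree + 1), interior, rep(boundary[2], degree + 1))
}

bspline_eval <- function(knots, v, degree, deriv = 0) {
  boundary <- range(knots)
  v <- pmin(pmax(v, boundary[1]), boundary[2])
  splines::splineDesign(knots, v, ord = degree + 1, derivs = deriv,
                        outer.ok = FALSE)
}

#' Sieve nonparametric IV (NPIV) with uniform confidence bands
#'
#' Approximates the structural function with a B-spline basis in the
#' exposure, instrumented by a richer B-spline basis in the instrument:
#' stage one projects each exposure-basis column on the instrument basis,
#' stage two regresses the outcome on the projected basis. The derivative of
#' the structural function comes from the analytic spline derivative basis,
#' with heteroskedasticity-robust pointwise bands and uniform bands from a
#' Gaussian multiplier bootstrap of the sup-t statistic over the evaluation
#' grid.
#'
#' Decision rules replace p-values: the global null of no effect anywhere is
#' rejected when the uniform band excludes zero somewhere on the grid, and
#' linearity is rejected when no single derivative value is contained in the
#' bands everywhere (the band intersection over the grid is empty). Both use
#' the simultaneous (uniform) band, which is the coverage notion under which
#' those rules are coherent.
#'
#' Covariates are handled by residualizing exposure and outcome on them
#' before fitting.
#'
#' @inheritParams fit_polynomial_tsls
#' @param knots_x Interior knots of the exposure basis (cubic by default).
#' @param knots_z Interior knots of the instrument basis; must give at least
#'   as many instrument columns as exposure columns.
#' @param spline_degree Spline degree for both bases (3 = cubic; 1 with
#'   `knots_x = knots_z = 0` collapses to linear TSLS).
#' @param n_multiplier Multiplier-bootstrap draws for the uniform band.
#' @param uniform Compute the uniform band and decisions? Skipping it is
#'   cheaper when only point estimates are needed.
#' @return Classes `nlmr_npiv`, `nlmr_fit`, with `reject_overall` /
#'   `reject_nonlinear` logicals and a grid carrying both pointwise and
#'   uniform bands; `p_overall` / `p_nonlinear` are `NA` (band decisions
#'   stand in for them).
#' @export
fit_npiv <- function(data, knots_x = 4, knots_z = 5, spline_degree = 3,
                     covariates = NULL,
                     exposure = "x", outcome = "y", instrument = "z",
                     conf_level = 0.95, grid_size = 101,
                     n_multiplier = 1000, uniform = TRUE) {
  x <- col_vec(data, exposure)
  y <- col_vec(data, outcome)
  z <- col_vec(data, instrument)
  if (sd(x) == 0) abort("exposure is constant")
  if (sd(z) == 0) abort("instrument is constant")
  C <- covariate_matrix(data, covariates)
  if (!is.null(C)) {
    x <- residualize_covariates(x, C)
    y <- residualize_covariates(y, C)
  }
  kx <- bspline_knots(x, knots_x, spline_degree)
  kz <- bspline_knots(z, knots_z, spline_degree)
  Bx <- bspline_eval(kx, x, spline_degree)
  Bz <- bspline_eval(kz, z, spline_degree)
  if (ncol(Bz) < ncol(Bx)) {
    abort(sprintf("instrument basis (%d columns) must be at least as rich as the exposure basis (%d columns)",
                  ncol(Bz), ncol(Bx)))
  }
  qz <- qr(Bz)
  if (qz$rank < ncol(Bz)) {
    abort(sprintf("instrument basis is rank deficient (rank %d < %d columns)",
                  qz$rank, ncol(Bz)), class = "nlmrhet_rank")
  }
  Bhat <- qr.fitted(qz, Bx)
  q2 <- qr(Bhat)
  if (q2$rank < ncol(Bhat)) {
    abort(sprintf("projected exposure basis is rank deficient (rank %d < %d columns)",
                  q2$rank, ncol(Bhat)), class = "nlmrhet_rank")
  }
  gamma <- qr.coef(q2, y)
  e <- drop(y - Bx %*% gamma)          # structural residuals
  A <- solve(crossprod(Bhat))

  grid_x <- exposure_grid(x, grid_size)
  Gd <- bspline_eval(kx, grid_x, spline_degree, deriv = 1)
  est <- drop(Gd %*% gamma)
  # Influence matrix of the derivative at each grid point: M[g, i] is the
  # contribution of observation i, so Var = rowSums(M^2) and the multiplier
  # process is M %*% xi.
  M <- (Gd %*% A) %*% t(Bhat * e)
  se <- sqrt(pmax(rowSums(M^2), 0))
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  grid <- tibble(x = grid_x, estimate = est, se = se,
                 conf_low = est - zcrit * se, conf_high = est + zcrit * se)

  reject_overall <- NA
  reject_nonlinear <- NA
  crit_unif <- NA_real_
  if (uniform) {
    n <- length(y)
    sup_t <- numeric(n_multiplier)
    Mstd <- M / pmax(se, .Machine$double.xmin)   # rows studentized
    done <- 0
    chunk <- 250L
    while (done < n_multiplier) {
      k <- min(chunk, n_multiplier - done)
      Xi <- matrix(rnorm(n * k), n, k)
      TT <- Mstd %*% Xi
      sup_t[done + seq_len(k)] <- apply(abs(TT), 2, max)
      done <- done + k
    }
    crit_unif <- quantile(sup_t, conf_level, names = FALSE)
    grid$unif_low <- est - crit_unif * se
    grid$unif_high <- est + crit_unif * se
    reject_overall <- any(grid$unif_low > 0 | grid$unif_high < 0)
    reject_nonlinear <- max(grid$unif_low) > min(grid$unif_high)
  }

  fit <- new_causal_fit(
    "npiv", gamma, A %*% crossprod(Bhat * e) %*% A,
    exposure_idx = seq_along(gamma), degree = NA_integer_,
    grid, conf_level, p_overall = NA_real_, p_nonlinear = NA_real_,
    diagnostics = list(knots_x = kx, knots_z = kz,
                       spline_degree = spline_degree,
                       basis_dim = c(J = ncol(Bx), K = ncol(Bz)),
                       condition_number = kappa(Bhat, exact = FALSE),
                       n = length(y)),
    extra = list(reject_overall = reject_overall,
                 reject_nonlinear = reject_nonlinear,
                 crit_uniform = crit_unif)
  )
  fit
}
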
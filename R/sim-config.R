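#' Define a simulation scenario
#'
#' A scenario bundles the generative parameters for one simulated population:
#' cohort size, number of causal variants, the partition of exposure
#' heritability into a homogeneous component and two interaction components
#' (variant-by-confounder, "G\eqn{\times}U", and variant-by-environment,
#' "G\eqn{\times}E"), the mixture proportions governing whether interaction
#' effects are directional (proportional to the homogeneous effects) or
#' balanced (independent, mean zero), confounder effects on exposure and
#' outcome, and the shape of the causal exposure-outcome function.
#'
#' The exposure model for individual \eqn{i} with standardized genotypes
#' \eqn{\tilde G_{ij}} is
#' \deqn{X_i = \sum_j (\beta_j + \tau_j U_i + \omega_j \epsilon_{X,i})
#'   \tilde G_{ij} + \phi_X U_i + \epsilon_{X,i},}
#' and the outcome model is \eqn{Y_i = h(X_i) + \phi_Y U_i + \epsilon_{Y,i}}.
#' Residual variances are chosen so that both traits have total variance one.
#' Note that \eqn{\epsilon_{X,i}} appears both inside the interaction sum and
#' as the additive residual: it is the *same* draw per individual, so the
#' variant-by-environment interaction shares its noise with the exposure
#' residual.
#'
#' @param n_per_cohort Individuals per cohort (each replicate simulates a
#'   discovery and an evaluation cohort of this size).
#' @param n_variants Number of independent causal variants \eqn{J}.
#' @param h2_hom Homogeneous exposure heritability \eqn{h^2_{X,hom}}.
#' @param h2_gxu Heritability from variant-by-confounder interaction.
#' @param h2_gxe Heritability from variant-by-environment interaction.
#' @param pi_tau Probability that a variant's \eqn{\tau_j} draws the
#'   directional (point-mass) mixture component; 0 gives fully balanced and 1
#'   fully directional heterogeneity.
#' @param pi_omega Same for \eqn{\omega_j}.
#' @param phi_x,phi_y Confounder effects on exposure and outcome.
#' @param causal_shape One of `"null"`, `"linear"`, `"quad_symmetric"`,
#'   `"quad_asymmetric"`: \eqn{h(x) = 0}, \eqn{c_1 x}, \eqn{c_2 x^2},
#'   \eqn{c_2 x^2 + c_1 x} respectively.
#' @param c1,c2 Linear and quadratic causal coefficients.
#' @param seed Integer seed; all randomness in [generate_cohort_pair()] is
#'   derived from it through named substreams.
#'
#' @return An object of class `nlmr_config` (a named list).
#' @examples
#' cfg <- sim_config(n_per_cohort = 1000, n_variants = 50, seed = 1)
#' cfg$h2_hom
#' @export
sim_config <- function(n_per_cohort = 50000,
                       n_variants = 1000,
                       h2_hom = 0.1,
                       h2_gxu = 0,
                       h2_gxe = 0,
                       pi_tau = 1,
                       pi_omega = 1,
                       phi_x = 0.05,
                       phi_y = 0.05,
                       causal_shape = c("null", "linear", "quad_symmetric",
                                        "quad_asymmetric"),
                       c1 = 0.05,
                       c2 = 0.05,
                       seed = 1L) {
  causal_shape <- match.arg(causal_shape)
  stopifnot(n_per_cohort >= 1, n_variants >= 1)
  for (p in c(h2_hom = h2_hom, h2_gxu = h2_gxu, h2_gxe = h2_gxe,
              pi_tau = pi_tau, pi_omega = pi_omega)) {
    if (p < 0 || p > 1) abort("heritabilities and mixture proportions must lie in [0, 1]")
  }
  h2_x <- h2_hom + h2_gxu + h2_gxe
  if (h2_x + phi_x^2 >= 1) {
    abort("h2_hom + h2_gxu + h2_gxe + phi_x^2 must be < 1 so the exposure residual variance is positive",
          class = "nlmrhet_config_error")
  }
  if (h2_hom == 0 &&
      ((pi_tau > 0 && h2_gxu > 0) || (pi_omega > 0 && h2_gxe > 0))) {
    abort("directional interaction effects require h2_hom > 0 (the directional scaling divides by h2_hom)",
          class = "nlmrhet_config_error")
  }
  structure(
    list(n_per_cohort = as.integer(n_per_cohort),
         n_variants = as.integer(n_variants),
         h2_hom = h2_hom, h2_gxu = h2_gxu, h2_gxe = h2_gxe,
         pi_tau = pi_tau, pi_omega = pi_omega,
         phi_x = phi_x, phi_y = phi_y,
         causal_shape = causal_shape, c1 = c1, c2 = c2,
         sigma2_x = 1 - h2_x - phi_x^2,
         seed = as.integer(seed)),
    class = "nlmr_config"
  )
}

#' @export
print.nlmr_config <- function(x, ...) {
  cat("<nlmr_config>\n")
  cat(sprintf("  n per cohort: %d, variants: %d\n", x$n_per_cohort, x$n_variants))
  cat(sprintf("  h2 hom/GxU/GxE: %.3g / %.3g / %.3g  (sigma2_x = %.3g)\n",
              x$h2_hom, x$h2_gxu, x$h2_gxe, x$sigma2_x))
  cat(sprintf("  pi_tau: %.2f, pi_omega: %.2f, phi_x: %.3g, phi_y: %.3g\n",
              x$pi_tau, x$pi_omega, x$phi_x, x$phi_y))
  cat(sprintf("  causal shape: %s (c1 = %.3g, c2 = %.3g), seed: %d\n",
              x$causal_shape, x$c1, x$c2, x$seed))
  invisible(x)
}

#' True causal derivative of the exposure-outcome function
#'
#' Evaluates \eqn{\partial h(x) / \partial x} for the four built-in causal
#' shapes.
#'
#' @param shape Causal shape label (see [sim_config()]).
#' @param x Numeric vector of exposure values.
#' @param c1,c2 Causal coefficients.
#' @return Numeric vector of derivatives, recycled to `length(x)`.
#' @examples
#' true_derivative("quad_symmetric", c(-1, 0, 1))
#' @export
true_derivative <- function(shape, x, c1 = 0.05, c2 = 0.05) {
  switch(shape,
    null = rep(0, length(x)),
    linear = rep(c1, length(x)),
    quad_symmetric = 2 * c2 * x,
    quad_asymmetric = 2 * c2 * x + c1,
    abort(paste0("unknown causal shape: ", shape))
  )
}

causal_function <- function(shape, c1 = 0.05, c2 = 0.05) {
  switch(shape,
    null = function(x) rep(0, length(x)),
    linear = function(x) c1 * x,
    quad_symmetric = function(x) c2 * x^2,
    quad_asymmetric = function(x) c2 * x^2 + c1 * x,
    abort(paste0("unknown causal shape: ", shape))
  )
}
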
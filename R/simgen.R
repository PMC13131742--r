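#' Sample a standardized genotype panel
#'
#' Allele frequencies are drawn from Beta(1, 5), raw genotypes from
#' Binomial(2, f_j), and each column is standardized with the *population*
#' frequency: \eqn{\tilde G = (G - 2f_j)/\sqrt{2 f_j (1 - f_j)}}. Using the
#' population frequency (never the sample frequency) keeps standardization
#' well defined even when a column happens to be monomorphic at small n;
#' degenerate frequency draws (numerically 0 or 1) are resampled.
#'
#' Uses the current RNG state; seed management lives in
#' [generate_cohort_pair()].
#'
#' @param n Number of individuals.
#' @param n_variants Number of variants J.
#' @param freqs Optional fixed allele-frequency vector (length `n_variants`),
#'   mainly for testing; values must lie strictly in (0, 1).
#' @return A list of class `nlmr_genotypes` with elements `freqs` (length J)
#'   and `geno_std` (n x J matrix).
#' @examples
#' set.seed(1)
#' g <- sample_genotypes(100, 5)
#' dim(g$geno_std)
#' @export
sample_genotypes <- function(n, n_variants, freqs = NULL) {
  stopifnot(n >= 1, n_variants >= 1)
  if (is.null(freqs)) {
    freqs <- rbeta(n_variants, 1, 5)
    bad <- which(freqs <= .Machine$double.eps | freqs >= 1 - .Machine$double.eps)
    while (length(bad) > 0) {
      freqs[bad] <- rbeta(length(bad), 1, 5)
      bad <- which(freqs <= .Machine$double.eps | freqs >= 1 - .Machine$double.eps)
    }
  } else {
    stopifnot(length(freqs) == n_variants, all(freqs > 0), all(freqs < 1))
  }
  raw <- matrix(rbinom(n * n_variants, 2L, rep(freqs, each = n)),
                nrow = n, ncol = n_variants)
  centre <- rep(2 * freqs, each = n)
  scale <- rep(sqrt(2 * freqs * (1 - freqs)), each = n)
  geno_std <- (raw - centre) / scale
  structure(list(freqs = freqs, geno_std = geno_std),
            class = "nlmr_genotypes")
}

#' Draw per-variant effect sizes for one replicate
#'
#' Homogeneous effects are \eqn{\beta_j \sim N(0, h^2_{X,hom}/J)}. Interaction
#' effects come from two-component mixtures: with probability `pi_tau`
#' (`pi_omega`) a variant draws the *directional* point mass
#' \eqn{\tau_j = \sqrt{h^2_{G\times U}/h^2_{X,hom}}\,\beta_j}
#' (\eqn{\omega_j = \sqrt{(h^2_{G\times E}/\sigma^2_X)/h^2_{X,hom}}\,\beta_j}),
#' otherwise the *balanced* normal component
#' \eqn{N(0, h^2_{G\times U}/J)} (\eqn{N(0, (h^2_{G\times E}/\sigma^2_X)/J)}).
#' The directional scalings make the realized interaction variance match the
#' target heritability regardless of the mixture proportion.
#'
#' Uses the current RNG state.
#'
#' @param config An [sim_config()] object.
#' @return A tibble of class `nlmr_effects` with columns `variant`, `beta`,
#'   `tau`, `omega`, `dir_tau`, `dir_omega`, and attributes `sigma2_x`,
#'   `config`.
#' @export
draw_effect_profile <- function(config) {
  J <- config$n_variants
  beta <- rnorm(J, 0, sqrt(config$h2_hom / J))
  draw_mixture <- function(pi_dir, h2, scale_var) {
    # scale_var: variance of the per-individual multiplier the interaction
    # rides on (1 for U, sigma2_x for eps_X); directional scaling divides by
    # it so the component contributes h2 to Var(X).
    if (h2 == 0) {
      list(eff = rep(0, J), dir = rep(FALSE, J))
    } else {
      dir <- runif(J) < pi_dir
      eff <- rnorm(J, 0, sqrt((h2 / scale_var) / J))
      eff[dir] <- sqrt((h2 / scale_var) / config$h2_hom) * beta[dir]
      list(eff = eff, dir = dir)
    }
  }
  mix_tau <- draw_mixture(config$pi_tau, config$h2_gxu, 1)
  mix_omega <- draw_mixture(config$pi_omega, config$h2_gxe, config$sigma2_x)
  out <- tibble::tibble(
    variant = seq_len(J),
    beta = beta,
    tau = mix_tau$eff,
    omega = mix_omega$eff,
    dir_tau = mix_tau$dir,
    dir_omega = mix_omega$dir
  )
  attr(out, "sigma2_x") <- config$sigma2_x
  attr(out, "config") <- config
  class(out) <- c("nlmr_effects", class(out))
  out
}

#' Simulate exposure values
#'
#' Applies the structural exposure model; the environmental draw
#' \eqn{\epsilon_{X,i} \sim N(0, \sigma^2_X)} enters both inside the
#' variant-by-environment interaction sum and as the additive residual — the
#' same realization per individual.
#'
#' @param panel An `nlmr_genotypes` panel.
#' @param u Confounder vector (length n).
#' @param effects An `nlmr_effects` profile.
#' @param config The generating [sim_config()].
#' @return A tibble with columns `x` (exposure) and `eps_x` (the shared
#'   environmental draw), useful for exact reconstruction checks.
#' @export
simulate_exposure <- function(panel, u, effects, config) {
  G <- panel$geno_std
  stopifnot(nrow(G) == length(u), ncol(G) == nrow(effects))
  if (config$sigma2_x <= 0) {
    abort("exposure residual variance is not positive", class = "nlmrhet_config_error")
  }
  eps_x <- rnorm(length(u), 0, sqrt(config$sigma2_x))
  g_beta <- drop(G %*% effects$beta)
  g_tau <- drop(G %*% effects$tau)
  g_omega <- drop(G %*% effects$omega)
  x <- g_beta + u * g_tau + eps_x * g_omega + config$phi_x * u + eps_x
  tibble::tibble(x = x, eps_x = eps_x,
                 g_beta = g_beta, g_tau = g_tau, g_omega = g_omega)
}

#' Simulate outcome values
#'
#' \eqn{Y_i = h(X_i) + \phi_Y U_i + \epsilon_{Y,i}}. Because \eqn{h(X)}
#' correlates with U, the residual variance has no convenient closed form; it
#' is set empirically as \eqn{\sigma^2_Y = 1 - \widehat{Var}(h(X) + \phi_Y U)}
#' on the realized cohort so that the total outcome variance is one.
#'
#' @param x Exposure vector.
#' @param u Confounder vector.
#' @param config The generating [sim_config()].
#' @return A tibble with columns `y`, `eps_y`, and attribute `sigma2_y`.
#' @export
simulate_outcome <- function(x, u, config) {
  stopifnot(length(x) == length(u))
  h <- causal_function(config$causal_shape, config$c1, config$c2)
  signal <- h(x) + config$phi_y * u
  sigma2_y <- 1 - var(signal)
  if (sigma2_y < 0) {
    abort("Var(h(X) + phi_Y U) exceeds 1; outcome residual variance would be negative",
          class = "nlmrhet_config_error")
  }
  eps_y <- rnorm(length(x), 0, sqrt(sigma2_y))
  out <- tibble::tibble(y = signal + eps_y, eps_y = eps_y)
  attr(out, "sigma2_y") <- sigma2_y
  out
}

new_cohort <- function(panel, u, exposure, outcome, effects, config, role) {
  pheno <- tibble::tibble(
    id = seq_along(u),
    u = u,
    x = exposure$x,
    y = outcome$y,
    eps_x = exposure$eps_x,
    eps_y = outcome$eps_y
  )
  structure(
    list(pheno = pheno,
         genotypes = panel$geno_std,
         freqs = panel$freqs,
         effects = effects,
         components = exposure[c("g_beta", "g_tau", "g_omega")],
         sigma2_y = attr(outcome, "sigma2_y"),
         config = config,
         role = role),
    class = "nlmr_cohort"
  )
}

simulate_cohort <- function(config, effects, role, seed) {
  panel <- with_substream(seed, role, "genotypes", code = {
    sample_genotypes(config$n_per_cohort, config$n_variants)
  })
  u <- with_substream(seed, role, "confounder", code = rnorm(config$n_per_cohort))
  exposure <- with_substream(seed, role, "exposure", code = {
    simulate_exposure(panel, u, effects, config)
  })
  outcome <- with_substream(seed, role, "outcome", code = {
    simulate_outcome(exposure$x, u, config)
  })
  new_cohort(panel, u, exposure, outcome, effects, config, role)
}

#' Generate a discovery/evaluation cohort pair
#'
#' Simulates two independent cohorts (independent genotypes, confounders and
#' noise) sharing one realized effect profile — effect sizes are population
#' parameters, common to both samples. The discovery cohort is meant for the
#' instrument GWAS, the evaluation cohort for nonlinear MR estimation. All
#' randomness derives deterministically from `config$seed` through named
#' substreams (effects / per-cohort genotypes / confounder / noise), so adding
#' further draws downstream never perturbs the data generation.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `nlmr_cohort_pair` with elements `discovery` and
#'   `evaluation`, both `nlmr_cohort` objects.
#' @examples
#' cfg <- sim_config(n_per_cohort = 500, n_variants = 20, seed = 7)
#' pair <- generate_cohort_pair(cfg)
#' sapply(pair, function(co) var(co$pheno$x))
#' @export
generate_cohort_pair <- function(config) {
  stopifnot(inherits(config, "nlmr_config"))
  seed <- config$seed
  effects <- with_substream(seed, "effects", code = draw_effect_profile(config))
  out <- list(
    discovery = simulate_cohort(config, effects, "discovery", seed),
    evaluation = simulate_cohort(config, effects, "evaluation", seed)
  )
  class(out) <- "nlmr_cohort_pair"
  out
}

#' Generate a single cohort
#'
#' One simulated sample under the configured generative model, with a fresh
#' effect profile drawn from the config seed. Use [generate_cohort_pair()]
#' when a discovery/evaluation pair sharing one effect profile is needed.
#'
#' @param config An [sim_config()] object.
#' @param role Label stored on the cohort (`"evaluation"` by default).
#' @return An `nlmr_cohort`.
#' @export
generate_cohort <- function(config, role = "evaluation") {
  stopifnot(inherits(config, "nlmr_config"))
  effects <- with_substream(config$seed, "effects",
                            code = draw_effect_profile(config))
  simulate_cohort(config, effects, role, config$seed)
}

#' @export
print.nlmr_cohort <- function(x, ...) {
  cat(sprintf("<nlmr_cohort: %s> n = %d, J = %d, shape = %s\n",
              x$role, nrow(x$pheno), ncol(x$genotypes),
              x$config$causal_shape))
  print(head(x$pheno, 4))
  invisible(x)
}

#' @export
print.nlmr_cohort_pair <- function(x, ...) {
  cat("<nlmr_cohort_pair>\n")
  print(x$discovery)
  print(x$evaluation)
  invisible(x)
}

#' @export
as_tibble.nlmr_cohort <- function(x, ...) x$pheno

#' Write / read a cohort as delimited text
#'
#' The phenotype table (`<stem>_pheno.tsv`: id, u, x, y) and the per-variant
#' effect profile (`<stem>_effects.tsv`) are always written; the standardized
#' genotype matrix (`<stem>_geno.tsv`, one row per individual) is optional
#' because it is large.
#'
#' @param cohort An `nlmr_cohort`.
#' @param stem File-path stem.
#' @param genotypes Write the genotype matrix too?
#' @return `stem`, invisibly.
#' @export
write_cohort <- function(cohort, stem, genotypes = FALSE) {
  utils::write.table(cohort$pheno[c("id", "u", "x", "y")],
                     paste0(stem, "_pheno.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  eff <- tibble::as_tibble(cohort$effects)
  eff$f <- cohort$freqs
  utils::write.table(eff, paste0(stem, "_effects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (genotypes) {
    utils::write.table(cohort$genotypes, paste0(stem, "_geno.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(stem)
}
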
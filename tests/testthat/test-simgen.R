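test_that("standardized genotypes take the closed-form values implied by the population frequency", {
  set.seed(1)
  g <- sample_genotypes(5, 3, freqs = rep(0.5, 3))
  allowed <- (0:2 - 1) / sqrt(0.5)
  expect_true(all(apply(g$geno_std, 2, function(col) all(col %in% allowed))))
  expect_equal(dim(g$geno_std), c(5, 3))
})

test_that("genotype columns have mean ~0 and variance ~1 at large n, and are always finite", {
  set.seed(2)
  g <- sample_genotypes(100000, 1)
  f <- g$freqs
  # binomial moments: se(mean) = 1/sqrt(n), se(var) bounded by kurtosis term
  expect_lt(abs(mean(g$geno_std)), 4 / sqrt(100000))
  expect_lt(abs(var(g$geno_std[, 1]) - 1), 0.1)
  set.seed(3)
  g2 <- sample_genotypes(1000, 1000)
  expect_equal(dim(g2$geno_std), c(1000, 1000))
  expect_true(all(is.finite(g2$geno_std)))
  expect_true(all(g2$freqs > 0 & g2$freqs < 1))
})

test_that("effect profile obeys the mixture structure", {
  # no interaction heritability -> interaction effects identically zero
  set.seed(4)
  eff0 <- draw_effect_profile(sim_config(n_per_cohort = 10, n_variants = 50,
                                         h2_gxu = 0, h2_gxe = 0))
  expect_true(all(eff0$tau == 0))
  expect_true(all(eff0$omega == 0))

  # fully directional: tau_j / beta_j == sqrt(h2_gxu / h2_hom) exactly
  set.seed(5)
  cfg <- sim_config(n_per_cohort = 10, n_variants = 200, h2_gxu = 0.1,
                    pi_tau = 1)
  eff1 <- draw_effect_profile(cfg)
  expect_true(all(eff1$dir_tau))
  expect_equal(eff1$tau / eff1$beta, rep(1, 200), tolerance = 1e-12)

  # fully balanced: variance ~ h2_gxu / J, uncorrelated with beta
  set.seed(6)
  cfg0 <- sim_config(n_per_cohort = 10, n_variants = 1000, h2_gxu = 0.1,
                     pi_tau = 0)
  taus <- replicate(30, {
    e <- draw_effect_profile(cfg0)
    c(var(e$tau), cor(e$beta, e$tau))
  })
  expect_equal(mean(taus[1, ]), 0.1 / 1000, tolerance = 0.1)
  expect_lt(abs(mean(taus[2, ])), 3 / sqrt(30 * 1000))
})

test_that("directional point mass is rejected when the homogeneous component is absent", {
  expect_error(
    sim_config(n_per_cohort = 10, n_variants = 10, h2_hom = 0, h2_gxu = 0.1,
               pi_tau = 0.5),
    class = "nlmrhet_config_error"
  )
})

test_that("degenerate exposure model reduces to pure environmental noise", {
  cfg <- sim_config(n_per_cohort = 50000, n_variants = 5, h2_hom = 0,
                    h2_gxu = 0, h2_gxe = 0, pi_tau = 0, pi_omega = 0,
                    phi_x = 0)
  set.seed(7)
  panel <- sample_genotypes(cfg$n_per_cohort, 5)
  u <- rnorm(cfg$n_per_cohort)
  eff <- draw_effect_profile(cfg)
  eff$beta <- rep(0, 5)
  ex <- simulate_exposure(panel, u, eff, cfg)
  expect_equal(ex$x, ex$eps_x)
  expect_equal(var(ex$x), 1, tolerance = 0.05)
})

test_that("exposure variance decomposition holds under homogeneity", {
  cfg <- scaled_config(21, n = 100000)
  pair <- generate_cohort_pair(cfg)
  ph <- pair$evaluation$pheno
  expect_equal(var(ph$x), 1, tolerance = 0.03)
  expect_lt(abs(cov(ph$x, ph$u) - cfg$phi_x), 0.012)
})

test_that("outcome variance is ~1 for every causal shape and Cov(Y,X) follows the covariance algebra", {
  for (shape in c("null", "linear", "quad_symmetric", "quad_asymmetric")) {
    cfg <- scaled_config(22, shape = shape, n = 100000)
    pair <- generate_cohort_pair(cfg)
    ph <- pair$evaluation$pheno
    expect_equal(var(ph$y), 1, tolerance = 0.03)
    if (shape == "null") {
      cfg0 <- sim_config(n_per_cohort = 100000, n_variants = 200,
                         causal_shape = "null", phi_y = 0, seed = 23)
      ph0 <- generate_cohort_pair(cfg0)$evaluation$pheno
      expect_lt(abs(cor(ph0$x, ph0$y)), 0.01)
    }
    if (shape == "linear") {
      # Cov(Y, X) = c1 Var(X) + phi_Y Cov(U, X) = 0.05 + 0.05 * 0.05
      expect_lt(abs(cov(ph$y, ph$x) - (0.05 + 0.05 * cfg$phi_x)), 0.012)
    }
  }
})

test_that("exposure reconstructs exactly from stored components (shared noise draw)", {
  cfg <- scaled_config(24, het = "gxe", pi = 1, n = 2000, J = 50)
  co <- generate_cohort_pair(cfg)$evaluation
  ph <- co$pheno
  cmp <- co$components
  x_rebuilt <- cmp$g_beta + ph$u * cmp$g_tau + ph$eps_x * cmp$g_omega +
    cfg$phi_x * ph$u + ph$eps_x
  expect_equal(ph$x, x_rebuilt, tolerance = 1e-12)
})

test_that("cohort pairs are deterministic in the seed and share the effect profile", {
  cfg <- scaled_config(31, n = 500, J = 30)
  p1 <- generate_cohort_pair(cfg)
  p2 <- generate_cohort_pair(cfg)
  expect_identical(p1$discovery$genotypes, p2$discovery$genotypes)
  expect_identical(p1$evaluation$pheno, p2$evaluation$pheno)
  expect_identical(p1$discovery$effects$beta, p1$evaluation$effects$beta)
  cfg2 <- scaled_config(32, n = 500, J = 30)
  p3 <- generate_cohort_pair(cfg2)
  expect_false(identical(p1$discovery$genotypes, p3$discovery$genotypes))
  # discovery and evaluation draws are independent
  expect_false(identical(p1$discovery$genotypes, p1$evaluation$genotypes))
})

test_that("variance bookkeeping holds on average across replicates and scenarios", {
  scenarios <- list(
    scaled_config(41, shape = "null"),
    scaled_config(42, shape = "linear", het = "gxu", pi = 1),
    scaled_config(43, shape = "quad_asymmetric", het = "gxe", pi = 0)
  )
  for (cfg in scenarios) {
    vx <- vy <- numeric(8)
    for (r in 1:8) {
      cfg$seed <- cfg$seed + r
      ph <- generate_cohort_pair(cfg)$evaluation$pheno
      vx[r] <- var(ph$x); vy[r] <- var(ph$y)
    }
    expect_equal(mean(vx), 1, tolerance = 0.02)
    expect_equal(mean(vy), 1, tolerance = 0.02)
  }
})

test_that("regressing X on the homogeneous genetic value recovers h2_hom", {
  r2 <- numeric(10)
  for (r in 1:10) {
    cfg <- scaled_config(50 + r)
    co <- generate_cohort_pair(cfg)$evaluation
    r2[r] <- summary(lm(co$pheno$x ~ co$components$g_beta))$r.squared
  }
  expect_lt(abs(mean(r2) - 0.1), 3 * sd(r2) / sqrt(10) + 0.005)
})

test_that("true derivatives match the four causal shapes", {
  expect_equal(true_derivative("null", c(-3, 7)), c(0, 0))
  expect_equal(true_derivative("linear", 2, c1 = 0.05), 0.05)
  expect_equal(true_derivative("quad_symmetric", 1, c2 = 0.05), 0.1)
  expect_equal(true_derivative("quad_asymmetric", 0, c1 = 0.05, c2 = 0.05), 0.05)
})

test_that("directional GxU makes the genetic-value slope increase across confounder tertiles", {
  cfg <- scaled_config(61, het = "gxu", pi = 1, n = 30000)
  co <- generate_cohort_pair(cfg)$evaluation
  ph <- co$pheno
  gv <- co$components$g_beta
  tert <- cut(ph$u, quantile(ph$u, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
              labels = FALSE)
  slopes <- sapply(1:3, function(k) {
    i <- tert == k
    coef(lm(ph$x[i] ~ gv[i]))[2]
  })
  # slope in tertile t is ~ 1 + sqrt(h2_gxu/h2_hom) * E(U | tertile)
  expect_true(slopes[1] < slopes[2], info = "slope increases with U")
  expect_true(slopes[2] < slopes[3])
  expect_equal(unname(slopes[3] - slopes[1]),
               1 * (mean(ph$u[tert == 3]) - mean(ph$u[tert == 1])),
               tolerance = 0.15)
})
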
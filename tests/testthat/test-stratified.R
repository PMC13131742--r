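test_that("residual stratification partitions the sample into near-equal quantile strata", {
  set.seed(121)
  d <- data.frame(z = rnorm(100))
  d$x <- 0.5 * d$z + rnorm(100)
  s <- residual_stratify(d, n_strata = 10)
  expect_equal(sort(unique(s$.stratum)), 1:10)
  expect_true(all(table(s$.stratum) == 10))
  # strata are ordered in the residual
  expect_true(all(diff(tapply(s$.resid, s$.stratum, max)) > 0))
  # mean exposure weakly increasing across residual strata
  mx <- tapply(s$x, s$.stratum, mean)
  expect_gt(cor(seq_along(mx), mx), 0.9)
  expect_error(residual_stratify(d, n_strata = 1))
})

test_that("degenerate residuals are flagged, not fatal", {
  d <- data.frame(z = rnorm(50))
  d$x <- d$z
  expect_warning(residual_stratify(d, n_strata = 5),
                 class = "nlmrhet_degenerate_strata")
})

test_that("doubly-ranked construction takes one member per pre-stratum", {
  set.seed(122)
  d <- data.frame(z = rnorm(9))
  d$x <- d$z + rnorm(9, sd = 0.01)
  s <- doubly_ranked_stratify(d, n_strata = 3)
  expect_true(all(table(s$.stratum) == 3))
  expect_true(all(table(s$.prestratum) == 3))
  # each final stratum contains exactly one member of every pre-stratum
  tab <- table(s$.stratum, s$.prestratum)
  expect_true(all(tab == 1))
  # X nearly monotone in Z: stratum = within-pre-stratum X rank, deterministic
  s2 <- doubly_ranked_stratify(d, n_strata = 3)
  expect_identical(s$.stratum, s2$.stratum)
  # remainder policy: n = 11, Q = 3 -> last pre-stratum has 5 members
  set.seed(123)
  d2 <- data.frame(z = rnorm(11))
  d2$x <- rnorm(11)
  s3 <- doubly_ranked_stratify(d2, n_strata = 3)
  expect_equal(as.vector(table(s3$.prestratum)), c(3, 3, 5))
  expect_equal(length(unique(s3$.stratum)), 3)
})

test_that("heterogeneity breaks rank preservation in the binary worked example", {
  # X = b1 Z + b2 D + b3 D Z + noise with binary Z and D and a large
  # interaction: X-ranks within instrument groups order by D when Z = 1 but
  # not detectably when Z = 0, so the rank-preservation assumption fails.
  set.seed(124)
  n <- 400
  z <- rbinom(n, 1, 0.5)
  d_mod <- rbinom(n, 1, 0.5)
  x <- 0.5 * z + 0.1 * d_mod + 3 * d_mod * z + rnorm(n, sd = 0.3)
  cor_z1 <- cor(rank(x[z == 1]), d_mod[z == 1])
  cor_z0 <- cor(rank(x[z == 0]), d_mod[z == 0])
  expect_gt(cor_z1, 0.8)
  expect_lt(cor_z0, 0.4)
})

test_that("stratum IV estimates recover a constant causal effect and its se", {
  set.seed(125)
  n <- 5000
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- 2 * x + rnorm(n)
  d <- data.frame(x = x, y = y, z = z)
  fit <- stratum_iv_estimates(residual_stratify(d, 5))
  expect_equal(nrow(fit$strata), 5)
  expect_equal(fit$strata$estimate, rep(2, 5), tolerance = 0.2)
  expect_lt(fit$p_overall, 1e-10)
  # matches a direct Wald ratio in one stratum
  i <- fit$assignment == 3
  expect_equal(fit$strata$estimate[3],
               cov(y[i], z[i]) / cov(x[i], z[i]), tolerance = 1e-10)
})

test_that("quadratic and Cochran Q tests match their closed forms", {
  fit <- structure(list(
    method = "fixture",
    strata = tibble::tibble(
      stratum = 1:2, n = c(50, 50), mean_x = c(-1, 1),
      estimate = c(0, 1), se = c(1, 1), statistic = c(0, 1),
      p_value = c(1, 0.32), conf_low = c(-2, -1), conf_high = c(2, 3),
      weak = c(FALSE, FALSE)),
    assignment = rep(1:2, each = 50),
    conf_level = 0.95, p_overall = NA_real_,
    p_nonlinear_quad = NA_real_, p_nonlinear_q = NA_real_),
    class = "nlmr_strat")
  # two strata: quadratic test not applicable
  expect_false(quadratic_test(fit)$applicable)
  # Cochran Q: IVW mean 0.5, Q = 0.5, p from chi-square(1)
  q <- cochran_q_test(fit)
  expect_equal(q$q, 0.5, tolerance = 1e-12)
  expect_equal(q$p_value, 0.4795001222, tolerance = 1e-8)
  # identical estimates: Q = 0, p = 1
  fit2 <- fit
  fit2$strata$estimate <- c(1, 1)
  expect_equal(cochran_q_test(fit2)$q, 0)
  expect_equal(cochran_q_test(fit2)$p_value, 1)
})

test_that("quadratic test tracks a linear trend in stratum estimates", {
  st <- tibble::tibble(
    stratum = 1:5, n = rep(100, 5), mean_x = seq(-2, 2),
    estimate = 0.3 * seq(-2, 2), se = rep(0.001, 5),
    statistic = NA_real_, p_value = rep(0.5, 5),
    conf_low = NA_real_, conf_high = NA_real_, weak = rep(FALSE, 5))
  fit <- structure(list(method = "fixture", strata = st,
                        assignment = rep(1:5, each = 100), conf_level = 0.95,
                        p_overall = NA_real_, p_nonlinear_quad = NA_real_,
                        p_nonlinear_q = NA_real_),
                   class = "nlmr_strat")
  res <- quadratic_test(fit)
  expect_equal(res$slope, 0.3, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-20)
  # all equal estimates with equal se: slope 0, p = 1
  st0 <- st
  st0$estimate <- rep(0.3, 5)
  fit0 <- fit
  fit0$strata <- st0
  res0 <- quadratic_test(fit0)
  expect_equal(res0$slope, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-10)
  # cross-check against metafor fixed-effect meta-regression
  skip_if_not_installed("metafor")
  rma <- suppressWarnings(
    metafor::rma(yi = st$estimate, sei = st$se, mods = ~ st$mean_x,
                 method = "FE"))
  expect_equal(res$slope, unname(rma$beta[2, 1]), tolerance = 1e-8)
  expect_equal(res$se, unname(rma$se[2]), tolerance = 1e-8)
})

test_that("Cauchy combination obeys its identities and the frozen numeric oracle", {
  expect_equal(cauchy_combine(0.5), 0.5, tolerance = 1e-12)
  for (p in c(0.01, 0.2, 0.9)) {
    expect_equal(cauchy_combine(c(p, p)), p, tolerance = 1e-10)
  }
  expect_equal(cauchy_combine(c(0.01, 0.5, 0.9)), 0.0331033664,
               tolerance = 1e-8)
  expect_error(cauchy_combine(numeric(0)))
  expect_warning(cauchy_combine(c(0, 0.5)), class = "nlmrhet_pvalue_clip")
  # weights shift the combination toward the up-weighted p-value
  expect_lt(cauchy_combine(c(0.001, 0.9), weights = c(10, 1)),
            cauchy_combine(c(0.001, 0.9)))
})

test_that("pooled stratum estimate agrees with linear TSLS under linear homogeneous truth", {
  d <- scored_evaluation(scaled_config(131, shape = "linear"))
  expect_false(is.null(d))
  fit <- fit_residual_stratification(d)
  st <- fit$strata[!fit$strata$weak, ]
  w <- 1 / st$se^2
  pooled <- sum(w * st$estimate) / sum(w)
  ts <- fit_polynomial_tsls(d, degree = 1)
  expect_equal(pooled, unname(ts$coefficients["x1"]), tolerance = 0.02)
})
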
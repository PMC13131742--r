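test_that("derivative metrics match hand algebra", {
  # exact estimate with a covering CI: bias 0, mse 0, coverage 1
  fit <- list(coefficients = c(`(Intercept)` = 0, x1 = 0.05),
              vcov = matrix(0.0001, 2, 2), exposure_idx = 2L,
              degree = 1L, conf_level = 0.95)
  class(fit) <- "nlmr_fit"
  x <- seq(-2, 2, length.out = 51)
  m <- derivative_metrics(fit, x, "linear", c1 = 0.05)
  expect_equal(m$bias, 0, tolerance = 1e-12)
  expect_equal(m$mse, 0, tolerance = 1e-12)
  expect_equal(m$coverage, 1)
  # constant estimate c against a derivative that is linear in x (symmetric
  # quadratic shape, d(x) = 0.1 x): bias = c - 0.1 * mean(x)
  fit2 <- fit
  fit2$coefficients <- c(`(Intercept)` = 0, x1 = 0.07)
  m2 <- derivative_metrics(fit2, x, "quad_symmetric", c2 = 0.05)
  expect_equal(m2$bias, 0.07 - 0.1 * mean(x), tolerance = 1e-12)
  expect_equal(m2$mse, mean((0.07 - 0.1 * x)^2), tolerance = 1e-12)
})

test_that("rejection rate and Wilson interval behave at the extremes and under the null", {
  expect_equal(rejection_rate(rep(1, 50))$rate, 0)
  expect_equal(rejection_rate(rep(0, 50))$rate, 1)
  set.seed(141)
  r <- rejection_rate(runif(1000))
  expect_lte(r$conf_low, 0.05 + 1e-12)
  expect_gte(r$conf_high, 0.05 - 1e-12)
  expect_error(rejection_rate(numeric(0)))
  expect_error(rejection_rate(c(0.5, 1.2)))
})

test_that("residualize_covariates strips covariate signal and handles collinearity", {
  set.seed(142)
  C <- cbind(a = rnorm(200), b = rnorm(200))
  y <- 2 + 3 * C[, 1] - C[, 2]
  r <- residualize_covariates(y, C)
  expect_equal(max(abs(r)), 0, tolerance = 1e-10)
  # intercept-only equivalent: centring
  y2 <- rnorm(200)
  r2 <- residualize_covariates(y2, matrix(1, 200, 1))
  expect_equal(r2, y2 - mean(y2), tolerance = 1e-12)
  # independent covariates leave the variance intact
  y3 <- rnorm(200)
  r3 <- residualize_covariates(y3, C)
  expect_equal(var(r3), var(y3), tolerance = 0.1)
  # collinear column dropped with a warning
  C2 <- cbind(C, c = C[, 1] + C[, 2])
  expect_warning(residualize_covariates(y3, C2),
                 class = "nlmrhet_collinear_dropped")
})

test_that("scenario grid builds unique labelled configs", {
  g <- scenario_grid(n_per_cohort = 1000, n_variants = 50,
                     shapes = c("null", "linear"))
  expect_equal(nrow(g), 10)
  expect_false(anyDuplicated(g$scenario) > 0)
  expect_true(all(purrr::map_lgl(g$config, inherits, "nlmr_config")))
  hom <- g$config[[which(g$scenario == "null/homogeneous")]]
  expect_equal(hom$h2_gxu, 0)
  expect_equal(hom$h2_hom, 0.1)
  dir_gxu <- g$config[[which(g$scenario == "null/gxu_pi1")]]
  expect_equal(dir_gxu$h2_gxu, 0.1)
  expect_equal(dir_gxu$pi_tau, 1)
})

test_that("run_grid is deterministic, shaped per scenario x replicate x method, and records failures", {
  g <- scenario_grid(n_per_cohort = 4000, n_variants = 100,
                     shapes = "linear",
                     het_settings = tibble::tibble(het = "none", pi = NA))
  r1 <- run_grid(g, methods = c("tsls_linear", "tsls_quad"), n_reps = 2,
                 seed = 5, compute_metrics = FALSE)
  expect_equal(nrow(r1), 4)
  r2 <- run_grid(g, methods = c("tsls_linear", "tsls_quad"), n_reps = 2,
                 seed = 5, compute_metrics = FALSE)
  expect_identical(r1$p_overall, r2$p_overall)
  # a tiny cohort with an impossible threshold: recorded, not fatal
  g2 <- scenario_grid(n_per_cohort = 200, n_variants = 20, shapes = "null",
                      het_settings = tibble::tibble(het = "none", pi = NA))
  r3 <- run_grid(g2, methods = "tsls_linear", n_reps = 2, seed = 5,
                 pgs_threshold = 1e-30, compute_metrics = FALSE)
  expect_true(all(r3$status == "no_instrument"))
  expect_true(all(is.na(r3$p_overall)))
})

test_that("screened analysis reduces to unscreened rates at threshold zero and produces diagonal Q-Q for uniform p", {
  set.seed(143)
  n <- 400
  fake <- tibble::tibble(
    scenario = "null/synthetic", shape = "null", het = "none",
    replicate = seq_len(n), method = "m1", status = "ok",
    p_overall = runif(n), p_nonlinear = runif(n),
    reject_overall = NA, reject_nonlinear = NA,
    p_nonlinear_q = NA_real_, bias = NA_real_, mse = NA_real_,
    coverage = NA_real_, n_eval = NA_integer_,
    bp_p = runif(n), n_selected = 10L)
  scr0 <- bp_screened_analysis(fake, bp_threshold = 0)
  expect_equal(scr0$rates$screened_rate, scr0$rates$unscreened_rate)
  expect_equal(scr0$rates$screened_n, scr0$rates$unscreened_n)
  scr <- bp_screened_analysis(fake, bp_threshold = 0.1)
  expect_lt(scr$rates$screened_n, n)
  # uniform p-values: Q-Q pairs hug the diagonal
  expect_lt(max(abs(scr$qq$expected - scr$qq$observed)), 0.12)
})

test_that("run_replicate returns one row per method with BP and selection metadata", {
  cfg <- scaled_config(144, shape = "linear", n = 8000, J = 100)
  out <- run_replicate(cfg, methods = c("tsls_linear", "strat_residual"),
                       compute_metrics = TRUE, cf_boot = 50)
  expect_equal(nrow(out), 2)
  expect_true(all(out$status == "ok"))
  expect_true(all(is.finite(out$bp_p)))
  expect_true(all(out$n_selected > 0))
  expect_true(is.finite(out$bias[out$method == "tsls_linear"]))
})
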
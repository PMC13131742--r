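#' Build a labelled scenario grid
#'
#' Crosses causal shapes with heterogeneity settings into a tibble of
#' labelled [sim_config()]s. Heterogeneity settings are supplied as a tibble
#' with columns `het` ("none", "gxu", "gxe") and `pi` (mixture proportion,
#' ignored for "none"); the defaults cover the homogeneous setting plus
#' balanced and directional variant-by-confounder and variant-by-environment
#' heterogeneity at heritability 0.1.
#'
#' @param n_per_cohort,n_variants Cohort size and variant count.
#' @param shapes Causal shapes to include.
#' @param het_settings Tibble of heterogeneity settings (see Details).
#' @param h2_het Interaction heritability used when a setting is active.
#' @param seed Base seed; each scenario/replicate derives substreams from it.
#' @param ... Further arguments passed to [sim_config()].
#' @return Tibble with columns `scenario`, `shape`, `het`, `pi`, `config`
#'   (list-column of `nlmr_config`).
#' @export
scenario_grid <- function(n_per_cohort = 50000, n_variants = 1000,
                          shapes = c("null", "linear", "quad_symmetric",
                                     "quad_asymmetric"),
                          het_settings = NULL,
                          h2_het = 0.1, seed = 1L, ...) {
  het_settings <- het_settings %||% tibble(
    het = c("none", "gxu", "gxu", "gxe", "gxe"),
    pi = c(NA, 0, 1, 0, 1)
  )
  grid <- tidyr::expand_grid(shape = shapes,
                             het_settings)
  grid$scenario <- paste0(
    grid$shape, "/",
    ifelse(grid$het == "none", "homogeneous",
           paste0(grid$het, "_pi", grid$pi))
  )
  grid$config <- purrr::pmap(grid[c("shape", "het", "pi")], function(shape, het, pi) {
    sim_config(
      n_per_cohort = n_per_cohort, n_variants = n_variants,
      h2_gxu = if (het == "gxu") h2_het else 0,
      h2_gxe = if (het == "gxe") h2_het else 0,
      pi_tau = if (het == "gxu") pi else 1,
      pi_omega = if (het == "gxe") pi else 1,
      causal_shape = shape, seed = seed, ...
    )
  })
  grid[c("scenario", "shape", "het", "pi", "config")]
}

method_roster <- function(methods) {
  known <- c("tsls_linear", "tsls_quad", "tsls_cubic", "tsls_aic",
             "cf_quad", "polymr", "polymr_sel", "npiv",
             "strat_residual", "strat_doubly_ranked")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", "),
                 "; available: ", paste(known, collapse = ", ")))
  }
  methods
}

fit_one_method <- function(method, d, covariates, n_strata, cf_boot,
                           npiv_uniform, polymr_degree) {
  switch(method,
    tsls_linear = fit_polynomial_tsls(d, degree = 1, covariates = covariates),
    tsls_quad = fit_polynomial_tsls(d, degree = 2, covariates = covariates),
    tsls_cubic = fit_polynomial_tsls(d, degree = 3, covariates = covariates),
    tsls_aic = select_degree_aic(d, covariates = covariates),
    cf_quad = fit_control_function(d, degree = 2, residual_degree = 1,
                                   instrument_degree = 2,
                                   covariates = covariates,
                                   se = "bootstrap", n_boot = cf_boot),
    polymr = fit_polymr(d, max_degree = polymr_degree,
                        model_selection = FALSE, covariates = covariates),
    polymr_sel = fit_polymr(d, max_degree = polymr_degree,
                            model_selection = TRUE, covariates = covariates),
    npiv = fit_npiv(d, covariates = covariates, uniform = npiv_uniform),
    strat_residual = fit_residual_stratification(d, n_strata = n_strata,
                                                 covariates = covariates),
    strat_doubly_ranked = fit_doubly_ranked(d, n_strata = n_strata,
                                            covariates = covariates)
  )
}

fit_summary_row <- function(method, fit, cohort, compute_metrics, alpha) {
  p_overall <- fit$p_overall %||% NA_real_
  p_nonlinear <- fit$p_nonlinear %||% NA_real_
  reject_overall <- NA
  reject_nonlinear <- NA
  if (inherits(fit, "nlmr_strat")) {
    p_overall <- fit$p_overall
    p_nonlinear <- fit$p_nonlinear_quad
  }
  if (inherits(fit, "nlmr_npiv")) {
    reject_overall <- fit$reject_overall
    reject_nonlinear <- fit$reject_nonlinear
  } else {
    reject_overall <- !is.na(p_overall) & p_overall < alpha
    reject_nonlinear <- if (is.na(p_nonlinear)) NA else p_nonlinear < alpha
  }
  metrics <- if (compute_metrics) {
    cfg <- cohort$config
    derivative_metrics(fit, cohort$pheno$x, cfg$causal_shape, cfg$c1, cfg$c2)
  } else {
    tibble(bias = NA_real_, mse = NA_real_, coverage = NA_real_,
           n_eval = NA_integer_)
  }
  extra <- if (inherits(fit, "nlmr_strat")) {
    tibble(p_nonlinear_q = fit$p_nonlinear_q)
  } else {
    tibble(p_nonlinear_q = NA_real_)
  }
  dplyr::bind_cols(
    tibble(method = method, status = "ok",
           p_overall = p_overall, p_nonlinear = p_nonlinear,
           reject_overall = reject_overall,
           reject_nonlinear = reject_nonlinear),
    extra, metrics
  )
}

failed_row <- function(method, status) {
  tibble(method = method, status = status,
         p_overall = NA_real_, p_nonlinear = NA_real_,
         reject_overall = NA, reject_nonlinear = NA,
         p_nonlinear_q = NA_real_,
         bias = NA_real_, mse = NA_real_, coverage = NA_real_,
         n_eval = NA_integer_)
}

#' Run one replicate of the simulation pipeline
#'
#' Generates a cohort pair, runs the discovery GWAS, builds the polygenic
#' score, screens with the Breusch-Pagan test on the evaluation cohort, fits
#' the requested methods and collects p-values, decisions and (optionally)
#' derivative bias/MSE/coverage. A replicate with no variant passing the
#' selection threshold is recorded with status `"no_instrument"` for every
#' method; failures of individual fits are recorded per method, never
#' aborting the replicate.
#'
#' @param config An [sim_config()]; its `seed` should already be
#'   replicate-specific (see [run_grid()]).
#' @param methods Character vector of method tags (see [run_grid()]).
#' @param pgs_threshold Selection threshold for the score.
#' @param compute_metrics Evaluate derivative bias/MSE/coverage?
#' @param alpha Nominal level used to turn p-values into decisions.
#' @param n_strata Strata for the stratification methods.
#' @param cf_boot Bootstrap resamples for the control-function covariance.
#' @param npiv_uniform Compute NPIV uniform bands (needed for its decisions)?
#' @param polymr_degree Maximum polynomial degree for PolyMR.
#' @return Tibble: one row per method plus columns `bp_p`, `n_selected`.
#' @export
run_replicate <- function(config, methods = c("tsls_quad", "cf_quad"),
                          pgs_threshold = 5e-8,
                          compute_metrics = TRUE, alpha = 0.05,
                          n_strata = 10, cf_boot = 200,
                          npiv_uniform = TRUE, polymr_degree = 10) {
  methods <- method_roster(methods)
  pair <- generate_cohort_pair(config)
  gwas <- run_gwas(pair$discovery)
  score <- tryCatch(
    select_and_score(gwas, pair$evaluation, threshold = pgs_threshold),
    error = function(e) {
      if (inherits(e, "nlmrhet_no_instrument")) NULL else stop(e)
    })
  if (is.null(score)) {
    out <- dplyr::bind_rows(purrr::map(methods, failed_row,
                                       status = "no_instrument"))
    out$bp_p <- NA_real_
    out$n_selected <- 0L
    return(out)
  }
  d <- pair$evaluation$pheno
  d$z <- score$score
  bp <- bp_screen(d)
  with_substream(config$seed, "fits", code = {
    rows <- purrr::map(methods, function(m) {
      fit <- tryCatch(
        suppressWarnings(fit_one_method(m, d, NULL, n_strata, cf_boot,
                                        npiv_uniform, polymr_degree)),
        error = function(e) NULL)
      if (is.null(fit)) {
        failed_row(m, "fit_error")
      } else {
        fit_summary_row(m, fit, pair$evaluation, compute_metrics, alpha)
      }
    })
    out <- dplyr::bind_rows(rows)
    out$bp_p <- bp$p_value
    out$n_selected <- length(score$selected)
    out
  })
}

#' Run a scenario grid
#'
#' Executes `n_reps` replicates of every scenario in a [scenario_grid()]
#' tibble and stacks the per-replicate method rows into one evaluation
#' table. Each replicate gets a deterministic seed derived from the base
#' `seed`, the scenario label and the replicate index, so the whole grid is
#' reproducible bit-for-bit and replicates are independent.
#'
#' Method tags: `tsls_linear`, `tsls_quad`, `tsls_cubic`, `tsls_aic`
#' (polynomial TSLS), `cf_quad` (quadratic control function with quadratic
#' control terms), `polymr` / `polymr_sel` (PolyMR without/with model
#' selection), `npiv` (sieve B-spline NPIV), `strat_residual`,
#' `strat_doubly_ranked`.
#'
#' @param grid A [scenario_grid()] tibble.
#' @param methods Method tags to fit.
#' @param n_reps Replicates per scenario.
#' @param seed Base seed for replicate substreams.
#' @param verbose Print one progress line per scenario?
#' @inheritParams run_replicate
#' @return Tibble: scenario metadata + replicate + per-method rows.
#' @export
run_grid <- function(grid, methods = c("tsls_quad", "cf_quad"),
                     n_reps = 100, seed = 1L,
                     pgs_threshold = 5e-8, compute_metrics = TRUE,
                     alpha = 0.05, n_strata = 10, cf_boot = 200,
                     npiv_uniform = TRUE, polymr_degree = 10,
                     verbose = FALSE) {
  stopifnot(all(c("scenario", "config") %in% names(grid)))
  if (anyDuplicated(grid$scenario)) abort("scenario labels must be unique")
  out <- purrr::map(seq_len(nrow(grid)), function(g) {
    label <- grid$scenario[g]
    cfg0 <- grid$config[[g]]
    if (verbose) message(sprintf("[%s] %d replicates", label, n_reps))
    reps <- purrr::map(seq_len(n_reps), function(r) {
      cfg <- cfg0
      cfg$seed <- substream_seed(seed, label, r)
      res <- run_replicate(cfg, methods, pgs_threshold, compute_metrics,
                           alpha, n_strata, cf_boot, npiv_uniform,
                           polymr_degree)
      res$replicate <- r
      res
    })
    reps <- dplyr::bind_rows(reps)
    reps$scenario <- label
    reps$shape <- grid$shape[g] %||% NA_character_
    reps$het <- grid$het[g] %||% NA_character_
    reps
  })
  dplyr::bind_rows(out)
}

#' Aggregate an evaluation table
#'
#' Per (scenario, method): mean bias and MSE with normal-theory CIs for the
#' mean, mean coverage, and rejection rates for the overall and nonlinearity
#' decisions, with the denominator of successful fits reported.
#'
#' @param results A [run_grid()] table.
#' @param conf_level Confidence level for the mean CIs.
#' @return Aggregated tibble.
#' @export
summarise_grid <- function(results, conf_level = 0.95) {
  zc <- qnorm(1 - (1 - conf_level) / 2)
  results %>%
    dplyr::group_by(scenario, method) %>%
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_ok = sum(status == "ok"),
      bias = mean(.data$bias[status == "ok"]),
      bias_se = sd(.data$bias[status == "ok"]) / sqrt(max(n_ok, 1)),
      mse = mean(.data$mse[status == "ok"]),
      mse_se = sd(.data$mse[status == "ok"]) / sqrt(max(n_ok, 1)),
      coverage = mean(.data$coverage[status == "ok"]),
      reject_overall = mean(.data$reject_overall[status == "ok"], na.rm = TRUE),
      reject_nonlinear = mean(.data$reject_nonlinear[status == "ok"], na.rm = TRUE),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      bias_low = bias - zc * bias_se, bias_high = bias + zc * bias_se,
      mse_low = mse - zc * mse_se, mse_high = mse + zc * mse_se
    )
}

#' Breusch-Pagan-screened calibration analysis
#'
#' Restricts null-scenario replicates to those whose Breusch-Pagan screen
#' did not signal heterogeneity (p above `bp_threshold`), recomputes
#' rejection rates per method, and emits expected-vs-observed p-value
#' quantile pairs pooled across heterogeneity settings for Q-Q plotting.
#' With `bp_threshold = 0` the screened rates equal the unscreened ones.
#'
#' @param results A [run_grid()] table of null-shape scenarios (rows with
#'   other shapes are ignored if a `shape` column is present).
#' @param bp_threshold Screen threshold (replicates with BP p >
#'   `bp_threshold` are kept).
#' @param alpha Nominal level.
#' @param test `"overall"` or `"nonlinear"`: which p-value column to screen.
#' @return List with tibbles `rates` (per method: screened and unscreened
#'   rejection with Wilson CIs and denominators) and `qq` (per method:
#'   expected and observed p-value quantiles among screened replicates).
#' @export
bp_screened_analysis <- function(results, bp_threshold = 0.1, alpha = 0.05,
                                 test = c("overall", "nonlinear")) {
  test <- match.arg(test)
  pcol <- if (test == "overall") "p_overall" else "p_nonlinear"
  d <- results
  if ("shape" %in% names(d) && any(!is.na(d$shape))) {
    d <- d[is.na(d$shape) | d$shape == "null", ]
  }
  d <- d[d$status == "ok" & !is.na(d[[pcol]]), ]
  if (nrow(d) == 0) abort("no usable null-scenario replicates")
  rates <- d %>%
    dplyr::group_by(method) %>%
    dplyr::group_modify(function(g, key) {
      unscr <- rejection_rate(g[[pcol]], alpha)
      # threshold 0 means no screening (BP p-values can underflow to 0)
      keep <- if (bp_threshold <= 0) rep(TRUE, nrow(g)) else g$bp_p > bp_threshold
      if (!any(keep, na.rm = TRUE)) {
        scr <- tibble(rate = NA_real_, n = 0L,
                      conf_low = NA_real_, conf_high = NA_real_)
      } else {
        scr <- rejection_rate(g[[pcol]][keep & !is.na(keep)], alpha)
      }
      tibble(unscreened_rate = unscr$rate, unscreened_n = unscr$n,
             screened_rate = scr$rate, screened_n = scr$n,
             screened_low = scr$conf_low, screened_high = scr$conf_high)
    }) %>%
    dplyr::ungroup()
  qq <- d %>%
    dplyr::filter(!is.na(bp_p) & (bp_threshold <= 0 | bp_p > bp_threshold)) %>%
    dplyr::group_by(method) %>%
    dplyr::group_modify(function(g, key) {
      p <- sort(g[[pcol]])
      tibble(expected = stats::ppoints(length(p)), observed = p)
    }) %>%
    dplyr::ungroup()
  list(rates = rates, qq = qq)
}
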
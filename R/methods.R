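#' Tidy a fitted nonlinear MR model
#'
#' Returns one row per model coefficient with delta-method standard errors
#' from the fit's covariance (bootstrap covariance for control-function fits
#' fitted with `se = "bootstrap"`).
#'
#' @param x An `nlmr_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `exposure_term`.
#' @export
tidy.nlmr_fit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(pmax(diag(x$vcov), 0))
  stat <- est / se
  tibble(term = names(est) %||% paste0("b", seq_along(est)),
         estimate = unname(est),
         std.error = unname(se),
         statistic = unname(stat),
         p.value = unname(2 * pnorm(-abs(stat))),
         exposure_term = seq_along(est) %in% x$exposure_idx)
}

#' Glance at a fitted nonlinear MR model
#'
#' @param x An `nlmr_fit` or `nlmr_strat`.
#' @param ... Unused.
#' @return One-row tibble with the method tag, degree / strata, the overall
#'   and nonlinearity p-values (or band decisions for NPIV) and diagnostics.
#' @export
glance.nlmr_fit <- function(x, ...) {
  tibble(method = x$method,
         degree = x$degree,
         p_overall = x$p_overall,
         p_nonlinear = x$p_nonlinear,
         reject_overall = x$reject_overall %||% NA,
         reject_nonlinear = x$reject_nonlinear %||% NA,
         condition_number = x$diagnostics$condition_number %||% NA_real_,
         nobs = x$diagnostics$n %||% NA_integer_)
}

#' @export
tidy.nlmr_strat <- function(x, ...) x$strata

#' @export
glance.nlmr_strat <- function(x, ...) {
  tibble(method = x$method,
         n_strata = nrow(x$strata),
         n_weak = sum(x$strata$weak),
         p_overall = x$p_overall,
         p_nonlinear_quad = x$p_nonlinear_quad,
         p_nonlinear_q = x$p_nonlinear_q,
         nobs = length(x$assignment))
}

#' @export
print.nlmr_fit <- function(x, ...) {
  cat(sprintf("<nlmr_fit: %s>", x$method))
  if (!is.na(x$degree %||% NA)) cat(sprintf(" degree %s", x$degree))
  cat("\n")
  print(tidy(x)[c("term", "estimate", "std.error", "p.value")], n = 12)
  if (!is.na(x$p_overall)) {
    cat(sprintf("p_overall = %.3g, p_nonlinear = %.3g\n",
                x$p_overall, x$p_nonlinear))
  }
  if (!is.null(x$reject_overall) && !is.na(x$reject_overall)) {
    cat(sprintf("uniform-band decisions: overall %s, nonlinearity %s\n",
                ifelse(x$reject_overall, "reject", "retain"),
                ifelse(x$reject_nonlinear, "reject", "retain")))
  }
  invisible(x)
}

#' Plot the estimated causal derivative with confidence bands
#'
#' @param object An `nlmr_fit`.
#' @param truth Optional function of x giving the true derivative, drawn
#'   dashed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nlmr_fit <- function(object, truth = NULL, ...) {
  g <- object$grid
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Exposure", y = "Causal derivative",
                  title = paste0("Estimated derivative (", object$method, ")")) +
    ggplot2::theme_minimal()
  if (all(c("unif_low", "unif_high") %in% names(g))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$unif_low,
                                               ymax = .data$unif_high),
                                  alpha = 0.1)
  }
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = truth(.data$x)),
                                linetype = "dashed")
  }
  p
}

#' Forest-style plot of stratum-specific causal estimates
#'
#' @param object An `nlmr_strat`.
#' @param ... Unused.
#' @return A ggplot of LACE estimates against stratum mean exposure.
#' @export
autoplot.nlmr_strat <- function(object, ...) {
  st <- object$strata[!object$strata$weak, ]
  ggplot2::ggplot(st, ggplot2::aes(x = .data$mean_x, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Stratum mean exposure",
                  y = "Stratum causal estimate (LACE)",
                  title = paste0("Stratified fit (", object$method, ")")) +
    ggplot2::theme_minimal()
}

#' Q-Q plot of screened null p-values
#'
#' @param qq The `qq` tibble from [bp_screened_analysis()].
#' @return A ggplot with one panel per method.
#' @export
plot_qq <- function(qq) {
  ggplot2::ggplot(qq, ggplot2::aes(x = -log10(.data$expected),
                                   y = -log10(.data$observed))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = expression(-log[10] ~ "expected p"),
                  y = expression(-log[10] ~ "observed p")) +
    ggplot2::theme_minimal()
}

#' Export a fitted derivative curve as delimited text
#'
#' Writes the evaluation grid (x, estimate, bands) and a one-row summary
#' (method, p-values, diagnostics) next to it.
#'
#' @param fit An `nlmr_fit`.
#' @param stem File-path stem; writes `<stem>_grid.tsv` and
#'   `<stem>_summary.tsv`.
#' @return `stem`, invisibly.
#' @export
write_fit <- function(fit, stem) {
  utils::write.table(fit$grid, paste0(stem, "_grid.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(glance(fit), paste0(stem, "_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
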
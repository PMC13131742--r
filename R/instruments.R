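#' Per-variant GWAS of the exposure
#'
#' Simple linear regression of the exposure on each standardized genotype
#' column, vectorized across variants; two-sided p-values from the t
#' statistic with n - 2 degrees of freedom. Zero-variance genotype columns
#' are flagged (`usable = FALSE`) and excluded from downstream selection.
#'
#' @param cohort An `nlmr_cohort` (normally the discovery cohort).
#' @return A tibble of class `nlmr_gwas` with columns `variant`, `estimate`,
#'   `se`, `statistic`, `p_value`, `usable`; attributes `n` and `role`.
#' @export
run_gwas <- function(cohort) {
  stopifnot(inherits(cohort, "nlmr_cohort"))
  G <- cohort$genotypes
  x <- cohort$pheno$x
  n <- length(x)
  if (n < 3) abort("GWAS requires at least 3 individuals")
  cm <- colMeans(G)
  sxx <- colSums(G^2) - n * cm^2
  xc <- x - mean(x)
  sxy <- drop(crossprod(G, xc))   # == sum((G - cm) * xc) since sum(xc) = 0
  syy <- sum(xc^2)
  usable <- sxx > .Machine$double.eps * n
  b <- ifelse(usable, sxy / sxx, NA_real_)
  rss <- syy - b^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tstat <- b / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- tibble(
    variant = seq_len(ncol(G)),
    estimate = b, se = se, statistic = tstat, p_value = p,
    usable = usable & is.finite(p)
  )
  attr(out, "n") <- n
  attr(out, "role") <- cohort$role
  class(out) <- c("nlmr_gwas", class(out))
  out
}

#' Build a polygenic-score instrument in the evaluation cohort
#'
#' Selects variants below the significance threshold in the discovery-cohort
#' GWAS and scores the *evaluation* cohort with the discovery-estimated
#' weights on standardized genotypes, then standardizes the score to mean
#' zero and variance one on the scoring sample. Selection and weights must
#' come from a different sample than the one being scored; scoring the cohort
#' the GWAS was run on is refused.
#'
#' @param gwas An `nlmr_gwas` from [run_gwas()] on the discovery cohort.
#' @param cohort The evaluation `nlmr_cohort` to score.
#' @param threshold Selection p-value threshold (genome-wide significance
#'   5e-8 by default).
#' @return A list of class `nlmr_score`: `score` (standardized, length n),
#'   `selected` (variant indices), `threshold`, `weights` (tibble).
#' @export
select_and_score <- function(gwas, cohort, threshold = 5e-8) {
  stopifnot(inherits(gwas, "nlmr_gwas"), inherits(cohort, "nlmr_cohort"))
  stopifnot(threshold > 0, threshold < 1)
  if (identical(attr(gwas, "role"), cohort$role)) {
    abort("refusing to score the same cohort the GWAS was estimated in; use independent discovery and evaluation cohorts",
          class = "nlmrhet_leakage")
  }
  sel <- which(gwas$usable & gwas$p_value < threshold)
  if (length(sel) == 0) {
    abort("no variant passed the selection threshold; increase the sample size or relax the threshold",
          class = "nlmrhet_no_instrument")
  }
  w <- gwas$estimate[sel]
  raw <- drop(cohort$genotypes[, sel, drop = FALSE] %*% w)
  score <- (raw - mean(raw)) / sd(raw)
  structure(
    list(score = score, selected = sel, threshold = threshold,
         weights = tibble(variant = sel, weight = w)),
    class = "nlmr_score"
  )
}

#' @export
print.nlmr_score <- function(x, ...) {
  cat(sprintf("<nlmr_score> %d variants selected at p < %g; n = %d\n",
              length(x$selected), x$threshold, length(x$score)))
  invisible(x)
}

#' Breusch-Pagan screen for instrument-exposure effect heterogeneity
#'
#' Under a homogeneous instrument effect the residuals of the linear
#' exposure-on-instrument regression are homoskedastic in the instrument;
#' interaction-driven heterogeneity makes the residual variance depend on the
#' instrument. The screen regresses the exposure on the instrument (plus
#' covariates) and applies the studentized (Koenker) Breusch-Pagan test of
#' the squared residuals on the same regressors, via [lmtest::bptest()].
#'
#' @param data Data frame containing the exposure, instrument and covariate
#'   columns.
#' @param exposure,instrument Column names (defaults `"x"`, `"z"`).
#' @param covariates Optional character vector of covariate column names.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @examples
#' d <- data.frame(z = rnorm(500))
#' d$x <- 0.3 * d$z + rnorm(500)
#' bp_screen(d)
#' @export
bp_screen <- function(data, exposure = "x", instrument = "z",
                      covariates = NULL) {
  x <- col_vec(data, exposure)
  z <- col_vec(data, instrument)
  if (sd(z) == 0) abort("instrument is constant")
  C <- covariate_matrix(data, covariates)
  df_fit <- data.frame(.x = x, .z = z)
  if (!is.null(C)) df_fit <- cbind(df_fit, as.data.frame(C))
  fit <- lm(.x ~ ., data = df_fit)
  bp <- lmtest::bptest(fit)   # default: studentized (Koenker) variant
  tibble(statistic = unname(bp$statistic),
         df = unname(bp$parameter),
         p_value = unname(bp$p.value),
         method = "studentized Breusch-Pagan")
}

#' Read or write GWAS summary statistics
#'
#' Delimited summary-statistics interchange (variant, estimate, se, p_value)
#' so externally estimated weights can replace the internal GWAS.
#'
#' @param gwas An `nlmr_gwas` tibble.
#' @param path File path (tab-separated).
#' @return `read_gwas()` returns an `nlmr_gwas` tibble; `write_gwas()` its
#'   input, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(gwas[c("variant", "estimate", "se", "p_value")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(gwas)
}

#' @rdname write_gwas
#' @param n Sample size to record on the imported object.
#' @export
read_gwas <- function(path, n = NA_integer_) {
  d <- utils::read.delim(path)
  stopifnot(all(c("variant", "estimate", "se", "p_value") %in% names(d)))
  out <- tibble(variant = d$variant, estimate = d$estimate, se = d$se,
                statistic = d$estimate / d$se, p_value = d$p_value,
                usable = is.finite(d$p_value) & d$se > 0)
  attr(out, "n") <- n
  attr(out, "role") <- "external"
  class(out) <- c("nlmr_gwas", class(out))
  out
}
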
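#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
NULL

#' @importFrom dplyr %>% mutate filter group_by summarise arrange bind_rows
#'   across all_of n
#' @importFrom stats lm lm.fit coef resid fitted var sd cov cor quantile
#'   rnorm runif rbeta rbinom pchisq pnorm pt qnorm setNames complete.cases
#' @importFrom utils head tail
NULL

# Deterministic sub-seed for a named random stream. Mixing stays below 2^53 so
# double arithmetic is exact; the result is a valid 32-bit seed.
substream_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h + 1) %% 2147483629)
}

with_substream <- function(seed, ..., code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, ...))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  code
}

# Raw polynomial design without intercept: columns x, x^2, ..., x^degree.
poly_raw <- function(x, degree, prefix = "x") {
  out <- vapply(seq_len(degree), function(j) x^j, numeric(length(x)))
  out <- matrix(out, ncol = degree)
  colnames(out) <- if (degree >= 1) paste0(prefix, seq_len(degree)) else NULL
  out
}

# Covariate matrix from column names of `data`; NULL when none requested.
covariate_matrix <- function(data, covariates) {
  if (is.null(covariates) || length(covariates) == 0) return(NULL)
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("covariate column(s) not found: ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[covariates])
  storage.mode(m) <- "double"
  check_full_rank(m, "covariates")
  m
}

check_full_rank <- function(m, what) {
  q <- qr(cbind(1, m))
  if (q$rank < ncol(m) + 1L) {
    bad <- colnames(m)[q$pivot[seq(q$rank + 1L, ncol(m) + 1L)] - 1L]
    abort(paste0("collinear ", what, ": ", paste(bad, collapse = ", ")),
          class = "nlmrhet_collinear")
  }
  invisible(m)
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(k, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

utils::globalVariables(c("method", "bp_p", "scenario"))

col_vec <- function(data, name) {
  if (!name %in% names(data)) abort(paste0("column `", name, "` not found"))
  v <- data[[name]]
  if (!is.numeric(v)) abort(paste0("column `", name, "` must be numeric"))
  as.numeric(v)
}
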
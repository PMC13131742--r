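# Shared small fixtures, built in code at test time.

# A small linear-IV data set with known structure: Z instrument, U confounder,
# X = a Z + U + noise, Y = b X - U + noise.
make_iv_data <- function(n = 2000, a = 0.5, b = 0.2, seed = 11) {
  set.seed(seed)
  z <- rnorm(n)
  u <- rnorm(n)
  x <- a * z + u + rnorm(n)
  y <- b * x - u + rnorm(n)
  tibble::tibble(x = x, y = y, z = z, u = u)
}

# Scaled scenario config used across simulation tests.
scaled_config <- function(seed, shape = "null", het = c("none", "gxu", "gxe"),
                          pi = 1, n = 20000, J = 200) {
  het <- match.arg(het)
  sim_config(
    n_per_cohort = n, n_variants = J,
    h2_gxu = if (het == "gxu") 0.1 else 0,
    h2_gxe = if (het == "gxe") 0.1 else 0,
    pi_tau = if (het == "gxu") pi else 1,
    pi_omega = if (het == "gxe") pi else 1,
    causal_shape = shape, seed = seed
  )
}

# Evaluation-cohort phenotype table with its PGS attached; NULL when no
# variant passes the selection threshold.
scored_evaluation <- function(config, threshold = 5e-8) {
  pair <- generate_cohort_pair(config)
  gwas <- run_gwas(pair$discovery)
  score <- tryCatch(select_and_score(gwas, pair$evaluation, threshold),
                    error = function(e) NULL)
  if (is.null(score)) return(NULL)
  d <- pair$evaluation$pheno
  d$z <- score$score
  attr(d, "cohort") <- pair$evaluation
  d
}
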
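# Shared fixtures and independent oracles for the suite.

toy_map_path <- system.file("extdata", "toy_phecode_map.csv", package = "phescreen")
toy_cui_path <- system.file("extdata", "toy_icd9_cui.csv", package = "phescreen")
toy_str_path <- system.file("extdata", "toy_cui_strings.csv", package = "phescreen")
toy_counts_path <- system.file("extdata", "toy_pubmed_counts.csv", package = "phescreen")

load_toy_map <- function() load_phecode_map(toy_map_path)
# concept tables are code-keyed: columns must stay character ("331.0" != 331)
load_toy_cui <- function() {
  readr::read_csv(toy_cui_path, col_types = "cc")
}
load_toy_strings <- function() {
  readr::read_csv(toy_str_path, col_types = "cc")
}

# subject-level aggregate matrix realizing a 2x2 table:
#   cases: a carriers / b non-carriers; controls: c carriers / d non-carriers
matrix_2x2 <- function(a, b, c, d, phecode = "200.1") {
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(a + b + c + d)),
    m = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    age = 50,
    sex = 1,
    y = rep(c(1L, 0L), c(a + b, c + d))
  ) |> dplyr::rename_with(~ phecode, "m")
}

# cross-product odds ratio: the closed-form oracle for covariate-free
# binary logistic regression on a 2x2 table
cross_product_or <- function(a, b, c, d) (a * d) / (b * c)

# Monte-Carlo oracle for P(p_delta = 0 | theta): simulate theta_hat draws and
# apply the decision rule (Wald interval disjoint from the null) directly.
mc_power <- function(theta, se, null, level = 0.95, n_draws = 1e5) {
  z <- qnorm(1 - (1 - level) / 2)
  th <- rnorm(n_draws, theta, se)
  mean(th + z * se < null$lo | th - z * se > null$hi)
}

# Monte-Carlo oracle for the empirical-Bayes PPV: uniform theta draws through
# the same decision rule, composed by the Bayes-factor formula.
mc_ppv <- function(ci_lo, ci_hi, null, pi0 = 0.5, level = 0.95, se = NULL,
                   n_draws = 1e6) {
  z <- qnorm(1 - (1 - level) / 2)
  if (is.null(se)) se <- (ci_hi - ci_lo) / (2 * z)
  # two-stage draw: true effect from the weight density, then the estimator
  # around it, then the interval-disjoint decision applied to the estimator
  rule <- function(theta) {
    th_hat <- rnorm(length(theta), theta, se)
    mean(th_hat + z * se < null$lo | th_hat - z * se > null$hi)
  }
  alpha <- rule(runif(n_draws, null$lo, null$hi))
  power1 <- rule(runif(n_draws, ci_lo, ci_hi))
  1 - 1 / (1 + (power1 / alpha) * ((1 - pi0) / pi0))
}

# Bernoulli carriage matrix for screen-level simulations (no visit layer):
# carriage probability p0 in controls and p1 in cases implies the given log-OR.
carriage_matrix <- function(n_per_arm, p0, log_or, phecode = "200.1") {
  odds1 <- p0 / (1 - p0) * exp(log_or)
  p1 <- odds1 / (1 + odds1)
  tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(2 * n_per_arm)),
    m = c(rbinom(n_per_arm, 1, p1), rbinom(n_per_arm, 1, p0)),
    age = 50,
    sex = 1,
    y = rep(c(1L, 0L), each = n_per_arm)
  ) |> dplyr::rename_with(~ phecode, "m")
}
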
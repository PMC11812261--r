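# Shared fixtures and independent oracles for the test suite.

# Minimal valid wide table of pairs; scores default to in-range constants.
make_pairs_df <- function(n = 4, zygosity = rep(c("MZ", "DZ"), length.out = n),
                          score = 2) {
  d <- data.frame(pair_id = paste0("p", seq_len(n)), zygosity = zygosity,
                  sex_t1 = "F", sex_t2 = "F",
                  age_16m = 15.8, age_5y = 5.15, age_12y = 12.69,
                  stringsAsFactors = FALSE)
  for (col in c("eoe_t1_16m", "eoe_t2_16m", "eoe_t1_5y", "eoe_t2_5y",
                "eoe_t1_12y", "eoe_t2_12y")) {
    d[[col]] <- score
  }
  d
}

# A well-conditioned set of generating paths (unit wave variances).
test_params <- function() {
  cholesky_params(a = c(0.55, 0.20, 0.10, 0.50, 0.15, 0.60),
                  c = c(0.60, 0.25, 0.20, 0.55, 0.20, 0.45),
                  e = c(0.58, 0.10, 0.05, 0.66, 0.10, 0.62),
                  means = c(0.2, -0.1, 0.3))
}

# Continuous-score simulation shortcut.
sim_twins <- function(params = test_params(), n_mz = 500, n_dz = 500,
                      retention = c(1, 1, 1), seed = 1) {
  cfg <- simulation_config(params, n_mz = n_mz, n_dz = n_dz,
                           wave_retention = retention, seed = seed)
  suppressMessages(simulate_cohort(cfg))
}

# Oracle: multivariate normal -2 log density, written directly from the
# density formula (solve/determinant), independent of the package path.
brute_neg2_logdens <- function(x, mu, sigma) {
  obs <- which(!is.na(x))
  d <- x[obs] - mu[obs]
  S <- sigma[obs, obs, drop = FALSE]
  length(obs) * log(2 * pi) + log(det(S)) + drop(t(d) %*% solve(S, d))
}

# Oracle: Pearson correlation from raw sums (no call to cor()).
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Oracle: OLS residuals via explicit normal equations.
brute_ols_residuals <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  drop(y - X %*% beta)
}

expect_all_lt <- function(x, bound) {
  expect_true(all(abs(x) < bound),
              info = sprintf("max |x| = %.4g (bound %.4g)", max(abs(x)), bound))
}
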
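test_that("free-parameter counts follow the model definitions", {
  expect_identical(count_free_parameters("saturated"), 54L)
  expect_identical(count_free_parameters("sub1a"), 42L)
  expect_identical(count_free_parameters("saturated_equal_order"), 42L)
  expect_identical(count_free_parameters("ace"), 21L)
  expect_identical(count_free_parameters("ace_cholesky"), 21L)
  expect_identical(count_free_parameters("sub1b"), 36L)
  expect_error(count_free_parameters("adce"), "unknown model kind")
  expect_error(count_free_parameters("ace", n_waves = 2), "three-wave")
})

test_that("moment-matched input recovers the generating parameters exactly", {
  truth <- test_params()
  S_mz <- build_expected_covariance(truth, 1.0)$sigma
  S_dz <- build_expected_covariance(truth, 0.5)$sigma
  mom <- twin_moments(S_mz, S_dz, 400, 800,
                      rep(truth$means, 2), rep(truth$means, 2))
  fit <- fit_model(mom, "ace", starts = 3, seed = 2)
  expect_true(fit$converged)
  for (m in c("a", "c", "e")) {
    expect_equal(fit$params[[m]], truth[[m]], tolerance = 1e-4)
  }
  expect_equal(fit$params$means, truth$means, tolerance = 1e-4)
  # at the optimum the fit cannot beat the generating parameters
  expect_lte(fit$minus2ll, fiml_minus2ll(truth, mom) + 1e-6)
})

test_that("simulated cohorts recover standardized components", {
  truth <- test_params()
  d <- sim_twins(truth, n_mz = 2000, n_dz = 2000, seed = 51)
  fit <- fit_model(d, "ace", starts = 1, seed = 51)
  expect_true(fit$converged)
  expect_all_lt(standardize(fit)$totals - standardize(truth)$totals, 0.05)

  # oracle: on complete data the FIML fit must coincide with the fit to the
  # exact empirical per-group moments
  Y <- twinace:::score_matrix(d)
  zyg <- d$data$zygosity
  mom_of <- function(g) {
    Yg <- Y[zyg == g, ]
    m <- colMeans(Yg)
    list(S = crossprod(sweep(Yg, 2, m)) / nrow(Yg), m = m, n = nrow(Yg))
  }
  mz <- mom_of("MZ"); dz <- mom_of("DZ")
  oracle <- fit_model(twin_moments(mz$S, dz$S, mz$n, dz$n, mz$m, dz$m),
                      "ace", starts = 1, seed = 51)
  expect_all_lt(standardize(fit)$totals - standardize(oracle)$totals, 1e-4)
  expect_equal(fit$minus2ll, oracle$minus2ll, tolerance = 1e-8)
})

test_that("the model ladder is monotone in -2LL and AIC is consistent", {
  d <- sim_twins(test_params(), n_mz = 250, n_dz = 350,
                 retention = c(1, 0.8, 0.6), seed = 52)
  fits <- lapply(c(saturated = "saturated", sub1a = "sub1a",
                   sub1b = "sub1b", ace = "ace"),
                 function(m) fit_model(d, m, seed = 5))
  for (f in fits) {
    expect_true(f$converged)
    expect_equal(f$aic, f$minus2ll + 2 * f$ep)
    expect_equal(f$df, f$nobs - f$ep)
  }
  tol <- 1e-4
  expect_lte(fits$saturated$minus2ll, fits$sub1a$minus2ll + tol)
  expect_lte(fits$sub1a$minus2ll, fits$sub1b$minus2ll + tol)
  expect_lte(fits$saturated$minus2ll, fits$ace$minus2ll + tol)

  cmp <- compare_models(fits$saturated, fits$sub1a)
  expect_equal(cmp$delta_df, 12L)
  expect_equal(cmp$delta_chi2, fits$sub1a$minus2ll - fits$saturated$minus2ll,
               tolerance = 1e-10)
  expect_equal(cmp$delta_aic, fits$sub1a$aic - fits$saturated$aic)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})

test_that("model comparison arithmetic handles edge cases", {
  d <- sim_twins(test_params(), n_mz = 150, n_dz = 150, seed = 53)
  full <- fit_model(d, "saturated", seed = 1)

  # equal fit, fewer parameters: delta = 0, p = 1
  nested <- full
  nested$model <- "sub1a"
  nested$ep <- 42L
  nested$aic <- nested$minus2ll + 2 * nested$ep
  cmp <- compare_models(full, nested)
  expect_equal(cmp$delta_chi2, 0)
  expect_equal(cmp$p_value, 1)

  # a "nested" model that fits better than the full one signals failure
  nested$minus2ll <- full$minus2ll - 1
  expect_error(compare_models(full, nested), "optimizer failure")

  nested$minus2ll <- full$minus2ll
  nested$ep <- 60L
  expect_error(compare_models(full, nested), "fewer parameters")

  nested$ep <- 42L
  nested$converged <- FALSE
  expect_error(compare_models(full, nested), "unconverged")
})

test_that("sign convention reports non-negative diagonal paths", {
  truth <- test_params()
  flipped <- cholesky_params(truth$a %*% diag(c(-1, 1, -1)),
                             truth$c %*% diag(c(1, -1, 1)),
                             truth$e, truth$means, normalize_signs = FALSE)
  S_mz <- build_expected_covariance(flipped, 1.0)$sigma
  S_dz <- build_expected_covariance(flipped, 0.5)$sigma
  mom <- twin_moments(S_mz, S_dz, 300, 600)
  fit <- fit_model(mom, "ace", starts = 3, seed = 4)
  expect_true(all(diag(fit$params$a) >= 0))
  expect_true(all(diag(fit$params$c) >= 0))
  expect_true(all(diag(fit$params$e) >= 0))
  # the flip is likelihood-invariant: implied covariance matches
  expect_equal(build_expected_covariance(fit$params, 1.0)$sigma, S_mz,
               tolerance = 1e-3)
})
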
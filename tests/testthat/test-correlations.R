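test_that("double-entry correlation matches a brute-force Pearson oracle", {
  # identical members
  est <- double_entry_correlation(c(1, 2, 3), c(1, 2, 3))
  expect_equal(est$r, 1)
  expect_equal(est$n_pairs, 3L)

  # oracle on the six double-entered points
  x <- c(1, 2, 1.5); y <- c(2, 1, 1.5)
  est <- double_entry_correlation(x, y)
  expect_equal(est$r, brute_pearson(c(x, y), c(y, x)), tolerance = 1e-12)

  # swap invariance
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    e1 <- double_entry_correlation(x, y)
    e2 <- double_entry_correlation(y, x)
    expect_equal(e1$r, e2$r, tolerance = 1e-12)
    expect_equal(e1$ci_low, e2$ci_low, tolerance = 1e-12)
  }

  # incomplete pairs are dropped before doubling
  est <- double_entry_correlation(c(1, 2, 3, NA, 5), c(1.1, 2.2, 2.9, 4, NA))
  expect_equal(est$n_pairs, 3L)

  expect_error(double_entry_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(double_entry_correlation(c(2, 2, 2), c(2, 2, 2)), "zero variance")
})

test_that("Fisher intervals match the closed form", {
  # half-width ~ z / sqrt(n - 3) near r = 0
  ci <- fisher_interval(0, 10003, 0.95)
  expect_equal(ci[1], -ci[2], tolerance = 1e-12)
  expect_equal(ci[2], tanh(qnorm(0.975) / 100), tolerance = 1e-12)
  expect_equal(ci[2], 0.0196, tolerance = 1e-3)

  expect_equal(fisher_interval(0.5, 100), c(0.335, 0.632), tolerance = 0.005)

  # level -> 1 gives the whole correlation range
  expect_equal(fisher_interval(0.3, 20, 1), c(-1, 1))

  expect_warning(ci <- fisher_interval(1, 50), "degenerate")
  expect_equal(ci, c(1, 1))
  expect_error(fisher_interval(0.2, 3), "at least 4")
  expect_error(fisher_interval(1.2, 50), "in \\[-1, 1\\]")
})

test_that("the report is symmetric with unit diagonal and honours duplication", {
  set.seed(5)
  n <- 40
  df <- make_pairs_df(n, zygosity = rep(c("MZ", "DZ"), n / 2))
  base <- matrix(rnorm(n * 3), n, 3)
  df$eoe_t1_16m <- df$eoe_t2_16m <- base[, 1]
  df$eoe_t1_5y <- df$eoe_t2_5y <- base[, 2]
  df$eoe_t1_12y <- df$eoe_t2_12y <- base[, 3]
  d <- twin_pairs(df, residualized = TRUE)
  suppressWarnings(rep <- correlation_report(d))
  for (g in c("MZ", "DZ")) {
    expect_identical(rep[[g]]$r, t(rep[[g]]$r))
    expect_equal(unname(diag(rep[[g]]$r)), rep(1, 6))
    # perfectly duplicated twins: intraclass cells are exactly 1
    expect_equal(unname(diag(rep[[g]]$r[4:6, 1:3])), rep(1, 3))
  }
  long <- as.data.frame(rep)
  expect_equal(nrow(long), 30L)
})

test_that("report cells approach the model-implied correlations", {
  params <- test_params()
  d <- sim_twins(params, n_mz = 6000, n_dz = 6000, seed = 21)
  r <- residualize_scores(d)
  rep <- correlation_report(r)
  for (g in c("MZ", "DZ")) {
    implied <- stats::cov2cor(
      build_expected_covariance(params, if (g == "MZ") 1.0 else 0.5)$sigma)
    expect_all_lt(rep[[g]]$r - implied, 0.04)
  }
})

test_that("pure nonshared-environment structure yields null cross-twin cells", {
  params <- cholesky_params(a = rep(0, 6), c = rep(0, 6), e = diag(3))
  d <- sim_twins(params, n_mz = 4000, n_dz = 4000, seed = 8)
  r <- residualize_scores(d)
  rep <- correlation_report(r)
  for (g in c("MZ", "DZ")) {
    expect_all_lt(rep[[g]]$r[4:6, 1:3], 0.05)
  }
})

test_that("unavailable cells are recorded missing with a warning", {
  df <- make_pairs_df(6, zygosity = rep(c("MZ", "DZ"), 3))
  for (col in grep("^eoe", names(df), value = TRUE)) df[[col]] <- rnorm(6)
  df$eoe_t1_12y <- df$eoe_t2_12y <- NA_real_
  df$eoe_t1_12y[1] <- 2  # keeps the wave from being empty but < 3 entries
  d <- twin_pairs(df, residualized = TRUE, range_check = FALSE)
  w <- capture_warnings(rep <- correlation_report(d))
  expect_true(any(grepl("unavailable", w)))
  expect_true(is.na(rep$MZ$r["t1_12y", "t2_12y"]))
  expect_equal(rep$MZ$r["t1_12y", "t1_12y"], 1)
})
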
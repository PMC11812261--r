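test_that("simulation is reproducible from the seed", {
  cfg <- gemini_like_config(n_mz = 150, n_dz = 300)
  d1 <- suppressMessages(simulate_cohort(cfg, seed = 5))
  d2 <- suppressMessages(simulate_cohort(cfg, seed = 5))
  d3 <- suppressMessages(simulate_cohort(cfg, seed = 6))
  expect_identical(d1$data, d2$data)
  expect_false(identical(d1$data, d3$data))
})

test_that("independence structure yields null twin correlations", {
  params <- cholesky_params(rep(0, 6), rep(0, 6), diag(3))
  d <- sim_twins(params, n_mz = 10000, n_dz = 10000, seed = 71)
  Y <- twinace:::score_matrix(d)
  for (g in c("MZ", "DZ")) {
    Yg <- Y[d$data$zygosity == g, ]
    for (w in 1:3) {
      r <- double_entry_correlation(Yg[, w], Yg[, w + 3])$r
      expect_lt(abs(r), 0.03)
    }
  }
})

test_that("pure additive-genetic structure reproduces twin relatedness", {
  params <- cholesky_params(diag(3), rep(0, 6), rep(0, 6))
  d <- sim_twins(params, n_mz = 10000, n_dz = 10000, seed = 72)
  Y <- twinace:::score_matrix(d)
  r_mz <- double_entry_correlation(Y[d$data$zygosity == "MZ", 1],
                                   Y[d$data$zygosity == "MZ", 4])$r
  r_dz <- double_entry_correlation(Y[d$data$zygosity == "DZ", 1],
                                   Y[d$data$zygosity == "DZ", 4])$r
  expect_equal(r_mz, 1, tolerance = 1e-2)
  expect_equal(r_dz, 0.5, tolerance = 0.02)
})

test_that("empirical moments converge to the expected covariance", {
  params <- test_params()
  sig <- build_expected_covariance(params, 1.0)$sigma
  frob <- function(n, seed) {
    d <- sim_twins(params, n_mz = n, n_dz = 50, seed = seed)
    Y <- twinace:::score_matrix(d)
    Yg <- Y[d$data$zygosity == "MZ", ]
    emp <- crossprod(sweep(Yg, 2, colMeans(Yg))) / nrow(Yg)
    sqrt(sum((emp - sig)^2))
  }
  ratios <- vapply(1:3, function(s) frob(8000, 100 + s) / frob(2000, 200 + s),
                   numeric(1))
  # quadrupling n should roughly halve the Frobenius error
  expect_lt(mean(ratios), 0.75)
})

test_that("the Gemini-like config reproduces published sample structure", {
  cfg <- gemini_like_config()
  expect_equal(cfg$n_mz + cfg$n_dz, 2402L)
  expect_equal(cfg$n_mz / (cfg$n_mz + cfg$n_dz), 0.3118, tolerance = 0.002)
  # retention schedule reproduces wave sizes in expectation at 4804 twins
  expect_equal(unname(cfg$wave_retention * 4804), c(3784, 2064, 964),
               tolerance = 1e-12)

  d <- suppressMessages(simulate_cohort(cfg, seed = 73))
  Y <- twinace:::score_matrix(d)
  counts <- colSums(!is.na(Y))[1:3] + colSums(!is.na(Y))[4:6]
  expect_all_lt(counts - c(3784, 2064, 964), 150)

  # Likert scores: bounded, item-grid valued, with published-like means
  expect_true(all(Y[!is.na(Y)] >= 1 & Y[!is.na(Y)] <= 5))
  means <- (colMeans(Y, na.rm = TRUE)[1:3] + colMeans(Y, na.rm = TRUE)[4:6]) / 2
  expect_true(all(means > 1.5 & means < 1.8))
})

test_that("the Gemini-like config reproduces the published twin correlations", {
  cfg <- gemini_like_config(n_mz = 16000, n_dz = 34000)
  d <- suppressMessages(simulate_cohort(cfg, seed = 74))
  r <- residualize_scores(d)
  rep <- correlation_report(r)
  pub <- published_eoe_correlations()
  expect_equal(rep$MZ$r["t2_16m", "t1_16m"], 0.97, tolerance = 0.02)
  expect_equal(rep$MZ$r["t2_5y", "t1_5y"], 0.98, tolerance = 0.025)
  expect_equal(rep$MZ$r["t2_12y", "t1_12y"], 0.95, tolerance = 0.02)
  expect_equal(rep$DZ$r["t2_16m", "t1_16m"], 0.92, tolerance = 0.02)
  expect_equal(rep$DZ$r["t2_12y", "t1_12y"], 0.73, tolerance = 0.025)
  # intraclass cells within +-0.02 overall at this scale
  expect_all_lt(diag(rep$MZ$r[4:6, 1:3]) - diag(pub$mz[4:6, 1:3]), 0.02)
  expect_all_lt(diag(rep$DZ$r[4:6, 1:3]) - diag(pub$dz[4:6, 1:3]), 0.02)
})

test_that("degenerate expected covariances are tolerated only when PSD", {
  params <- cholesky_params(diag(3), rep(0, 6), rep(0, 6))
  d <- sim_twins(params, n_mz = 10, n_dz = 10, seed = 75)
  Y <- twinace:::score_matrix(d)
  mz <- Y[d$data$zygosity == "MZ", ]
  expect_equal(unname(mz[, 1:3]), unname(mz[, 4:6]), tolerance = 1e-6)  # identical co-twins
})

test_that("likert settings validate threshold monotonicity", {
  expect_error(likert_settings(base = c(0, 0, 0), spacing = c(-1, 1, 1)),
               "spacing")
  lik <- likert_settings(base = c(0.1, 0.3, 0), spacing = c(0.9, 0.9, 0.9))
  expect_equal(lik$n_items, c(3L, 4L, 4L))
  expect_equal(dim(lik$thresholds[[2]]), c(4L, 4L))
  cfg <- gemini_like_config()
  cfg$likert$thresholds[[1]][1, ] <- c(1, 1, 1, 1)
  expect_error(simulation_config(cfg$params, 10, 10, likert = cfg$likert),
               "strictly increasing")
})
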
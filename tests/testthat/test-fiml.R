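test_that("FIML equals a per-pair brute-force density oracle", {
  params <- test_params()
  # complete data
  d <- sim_twins(params, n_mz = 150, n_dz = 150, seed = 31)
  got <- fiml_minus2ll(params, d)
  Y <- twinace:::score_matrix(d)
  zyg <- d$data$zygosity
  want <- 0
  for (g in c("MZ", "DZ")) {
    sig <- build_expected_covariance(params, if (g == "MZ") 1.0 else 0.5)
    Yg <- Y[zyg == g, , drop = FALSE]
    for (i in seq_len(nrow(Yg))) {
      want <- want + brute_neg2_logdens(Yg[i, ], sig$mu, sig$sigma)
    }
  }
  expect_equal(got, want, tolerance = 1e-9)

  # missing waves: observed-subvector densities
  dm <- sim_twins(params, n_mz = 120, n_dz = 120, retention = c(1, 0.6, 0.4),
                  seed = 32)
  got <- fiml_minus2ll(params, dm)
  Y <- twinace:::score_matrix(dm)
  zyg <- dm$data$zygosity
  want <- 0
  for (g in c("MZ", "DZ")) {
    sig <- build_expected_covariance(params, if (g == "MZ") 1.0 else 0.5)
    Yg <- Y[zyg == g, , drop = FALSE]
    for (i in seq_len(nrow(Yg))) {
      want <- want + brute_neg2_logdens(Yg[i, ], sig$mu, sig$sigma)
    }
  }
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("a pair with a single observed score adds one scalar Gaussian term", {
  params <- test_params()
  d <- sim_twins(params, n_mz = 40, n_dz = 40, seed = 33)
  base <- fiml_minus2ll(params, d)

  extra <- make_pairs_df(1, zygosity = "DZ")
  extra$pair_id <- "extra"
  for (col in grep("^eoe", names(extra), value = TRUE)) extra[[col]] <- NA_real_
  extra$eoe_t1_5y <- 2.4
  d2 <- d
  d2$data <- rbind(d$data, twin_pairs(extra, range_check = FALSE)$data)
  sig <- build_expected_covariance(params, 0.5)
  scalar <- log(2 * pi) + log(sig$sigma[2, 2]) +
    (2.4 - sig$mu[2])^2 / sig$sigma[2, 2]
  expect_equal(fiml_minus2ll(params, d2), base + scalar, tolerance = 1e-10)
})

test_that("inflating E eventually decreases the likelihood", {
  params <- test_params()
  d <- sim_twins(params, n_mz = 100, n_dz = 100, seed = 34)
  vals <- vapply(c(1, 5, 25, 125), function(t) {
    p <- cholesky_params(params$a, params$c, params$e * t, params$means)
    fiml_minus2ll(p, d)
  }, numeric(1))
  expect_true(vals[4] > vals[1])
  expect_true(all(diff(vals)[2:3] > 0))
})

test_that("summary moments reproduce the complete-data likelihood", {
  params <- test_params()
  d <- sim_twins(params, n_mz = 80, n_dz = 90, seed = 35)
  Y <- twinace:::score_matrix(d)
  zyg <- d$data$zygosity
  mom_of <- function(g) {
    Yg <- Y[zyg == g, ]
    m <- colMeans(Yg)
    list(S = crossprod(sweep(Yg, 2, m)) / nrow(Yg), m = m, n = nrow(Yg))
  }
  mz <- mom_of("MZ"); dz <- mom_of("DZ")
  mom <- twin_moments(mz$S, dz$S, mz$n, dz$n, mz$m, dz$m)
  expect_equal(fiml_minus2ll(params, mom), fiml_minus2ll(params, d),
               tolerance = 1e-9)
  expect_equal(mom$nobs, 6 * (mz$n + dz$n))
})

test_that("singular observed covariance yields a penalty, not an error", {
  p <- cholesky_params(a = diag(3), c = rep(0, 6), e = rep(0, 6))
  d <- sim_twins(test_params(), n_mz = 20, n_dz = 20, seed = 36)
  v <- fiml_minus2ll(p, d)
  expect_true(is.finite(v))
  expect_gte(v, 1e9)
})
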
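test_that("expected covariance reduces correctly in degenerate cases", {
  p_e <- cholesky_params(a = rep(0, 6), c = rep(0, 6), e = diag(3))
  expect_equal(unname(build_expected_covariance(p_e, 1.0)$sigma), diag(6))

  p_a <- cholesky_params(a = diag(3), c = rep(0, 6), e = rep(0, 6))
  s <- build_expected_covariance(p_a, 0.5)$sigma
  expect_equal(unname(s[1:3, 4:6]), 0.5 * diag(3))
  expect_equal(unname(s[1:3, 1:3]), diag(3))
})

test_that("expected covariance matches an element-wise block oracle", {
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(6, 0, 0.5); c_ <- rnorm(6, 0, 0.5); e <- rnorm(6, 0.8, 0.2)
    p <- cholesky_params(a, c_, e, normalize_signs = FALSE)
    for (rel in c(1.0, 0.5)) {
      got <- build_expected_covariance(p, rel)$sigma
      # oracle: explicit sums over factor origins
      blk <- function(m) {
        out <- matrix(0, 3, 3)
        for (r in 1:3) for (s in 1:3) out[r, s] <- sum(m[r, ] * m[s, ])
        out
      }
      A <- blk(p$a); C <- blk(p$c); E <- blk(p$e)
      want <- rbind(cbind(A + C + E, rel * A + C), cbind(rel * A + C, A + C + E))
      expect_equal(unname(got), want, tolerance = 1e-12)
      # symmetry, PSD, identical within-twin blocks
      expect_equal(got, t(got))
      expect_gte(min(eigen(got, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
      expect_equal(unname(got[1:3, 1:3]), unname(got[4:6, 4:6]))
    }
  }
  expect_error(build_expected_covariance(test_params(), 0.25), "relatedness")
})

test_that("standardized contributions are normalized and place carry-over shares", {
  # pure shared environment: C total 1 at every wave, no carried shares
  p_c <- cholesky_params(a = rep(0, 6), c = diag(3), e = rep(0, 6))
  v <- standardize(p_c)
  expect_equal(unname(v$totals[, "C"]), rep(1, 3))
  expect_equal(sum(v$origins$c[lower.tri(diag(3))]), 0)

  # normalization identity for arbitrary parameters
  set.seed(17)
  for (i in 1:20) {
    p <- cholesky_params(rnorm(6, 0, 0.6), rnorm(6, 0, 0.6), rnorm(6, 0.7, 0.3),
                         normalize_signs = FALSE)
    v <- standardize(p)
    per_wave <- rowSums(v$origins$a + v$origins$c + v$origins$e)
    expect_equal(unname(per_wave), rep(1, 3), tolerance = 1e-8)
    expect_true(all(v$origins$a >= 0 & v$origins$c >= 0 & v$origins$e >= 0))
    expect_equal(unname(rowSums(v$totals)), rep(1, 3), tolerance = 1e-8)
  }

  # a carried-over shared-environment path of sqrt(0.07) with unit wave-2
  # variance contributes a 7% share
  p <- cholesky_params(a = c(0, 0, 0, sqrt(0.20), 0, 1),
                       c = c(sqrt(0.89), sqrt(0.07), 0, sqrt(0.63), 0, 1),
                       e = c(sqrt(0.11), 0, 0, sqrt(0.10), 0, 1))
  v <- standardize(p)
  expect_equal(v$origins$c["5y", "16m"], 0.07, tolerance = 1e-12)

  expect_error(cholesky_params(rep(0, 6), rep(0, 6),
                               c(1, 0, 0, 0, 0, 1)),
               "positive")
})

test_that("Falconer arithmetic is exact and the clamped view is bounded", {
  f <- falconer_estimates(0.5, 0.25)
  expect_equal(c(f$A, f$C, f$E), c(0.5, 0, 0.5))

  f <- falconer_estimates(0.97, 0.92)
  expect_equal(c(f$A, f$C, f$E), c(0.10, 0.87, 0.03), tolerance = 1e-12)

  f <- falconer_estimates(0.95, 0.73)
  expect_equal(c(f$A, f$C, f$E), c(0.44, 0.51, 0.05), tolerance = 1e-12)

  # raw values are not truncated; the clamped view is
  f <- falconer_estimates(0.2, 0.8)
  expect_lt(f$A, 0)
  expect_equal(unname(f$clamped["A"]), 0)
  expect_error(falconer_estimates(1.2, 0.5), "\\[-1, 1\\]")
})
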
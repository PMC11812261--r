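# Full-information maximum likelihood machinery.
#
# Records are grouped by zygosity and missingness pattern; each pattern
# stores its observed slot indices and sufficient statistics (n, mean, MLE
# covariance). The FIML -2 log likelihood then reduces to
#   sum_k n_k [ p_k log(2 pi) + log det S_k + tr(S_k^-1 Sk) + quad_k ]
# over patterns, which is exact and much cheaper than per-row evaluation.

#' Summary-statistics input for twin model fitting
#'
#' Wraps per-group 6 x 6 sample covariance (or correlation) matrices and
#' sample sizes as a complete-data input for [fit_model()] and
#' [fiml_minus2ll()]. Under complete data these moments are the sufficient
#' statistics of the multivariate-normal likelihood, so fitting to them is
#' equivalent to fitting to raw data with those moments. This is the route
#' for re-analysing published twin correlation tables when raw data are
#' unavailable.
#'
#' @param S_mz,S_dz 6 x 6 symmetric positive-definite matrices over the
#'   slots (twin 1 x waves 16m/5y/12y, twin 2 x waves).
#' @param n_mz,n_dz Number of pairs per group.
#' @param mean_mz,mean_dz Observed 6-vector means (default zero, the
#'   correlation-matrix convention).
#' @return An object of class `twin_moments`.
#' @export
twin_moments <- function(S_mz, S_dz, n_mz, n_dz,
                         mean_mz = rep(0, 6), mean_dz = rep(0, 6)) {
  chk <- function(S, nm) {
    S <- as.matrix(S)
    if (!all(dim(S) == c(6L, 6L))) stopf("`%s` must be 6 x 6", nm)
    if (max(abs(S - t(S))) > 1e-8) stopf("`%s` must be symmetric", nm)
    symm(S)
  }
  S_mz <- chk(S_mz, "S_mz"); S_dz <- chk(S_dz, "S_dz")
  if (n_mz < 1 || n_dz < 1) stopf("group sizes must be positive")
  pat <- function(S, n, m) list(list(idx = 1:6, n = n, mean = as.numeric(m), S = S))
  structure(list(groups = list(MZ = pat(S_mz, n_mz, mean_mz),
                               DZ = pat(S_dz, n_dz, mean_dz)),
                 n_pairs = c(MZ = n_mz, DZ = n_dz),
                 nobs = 6 * (n_mz + n_dz)),
            class = "twin_moments")
}

# Convert a twin_pairs dataset to pattern-grouped sufficient statistics.
#' @noRd
as_twin_moments <- function(x) {
  if (inherits(x, "twin_moments")) return(x)
  stopifnot(inherits(x, "twin_pairs"))
  Y <- score_matrix(x)
  zyg <- x$data$zygosity
  one <- function(Yg) {
    if (nrow(Yg) == 0L) return(list())
    key <- apply(!is.na(Yg), 1L, paste, collapse = "")
    lapply(split(seq_len(nrow(Yg)), key), function(rows) {
      idx <- which(!is.na(Yg[rows[1L], ]))
      Z <- Yg[rows, idx, drop = FALSE]
      n <- nrow(Z)
      m <- colMeans(Z)
      Zc <- sweep(Z, 2L, m)
      list(idx = idx, n = n, mean = m, S = crossprod(Zc) / n)
    })
  }
  groups <- list(MZ = one(Y[zyg == "MZ", , drop = FALSE]),
                 DZ = one(Y[zyg == "DZ", , drop = FALSE]))
  structure(list(groups = groups,
                 n_pairs = c(MZ = sum(zyg == "MZ"), DZ = sum(zyg == "DZ")),
                 nobs = sum(!is.na(Y))),
            class = "twin_moments")
}

# -2LL of one group given model-implied mu (6-vector) and Sigma (6 x 6).
# Returns a large graded penalty instead of an error when an observed
# submatrix is not positive definite, keeping optimizers stable.
#' @noRd
neg2ll_group <- function(mu, sigma, patterns) {
  total <- 0
  if (any(!is.finite(mu)) || any(!is.finite(sigma))) return(1e12)
  for (p in patterns) {
    Si <- symm(sigma[p$idx, p$idx, drop = FALSE])
    ch <- tryCatch(chol(Si), error = function(e) NULL)
    if (is.null(ch)) {
      lam <- min(eigen(Si, symmetric = TRUE, only.values = TRUE)$values)
      return(1e10 * (1 + abs(lam)))
    }
    logdet <- 2 * sum(log(diag(ch)))
    inv <- chol2inv(ch)
    d <- p$mean - mu[p$idx]
    total <- total + p$n * (length(p$idx) * log(2 * pi) + logdet +
                              sum(inv * p$S) + drop(d %*% inv %*% d))
  }
  total
}

#' FIML -2 log likelihood of Cholesky ACE parameters
#'
#' Evaluates minus twice the full-information maximum-likelihood
#' log likelihood of a two-group (MZ relatedness 1.0, DZ relatedness 0.5)
#' Cholesky ACE model. Each pair contributes the multivariate-normal
#' density of its observed sub-vector under the zygosity-appropriate
#' expected covariance; pairs with missing waves therefore contribute
#' through the corresponding sub-matrix, without imputation.
#'
#' If an observed sub-matrix is numerically singular the function returns a
#' large penalty value rather than throwing, so that numerical optimizers
#' can recover; fits flag convergence separately.
#'
#' @param params A [cholesky_params] object.
#' @param data A [twin_pairs] dataset (every pair must have at least one
#'   observed score, which [twin_pairs()] enforces) or a [twin_moments]
#'   summary object.
#' @return The -2 log likelihood (scalar).
#' @export
fiml_minus2ll <- function(params, data) {
  stopifnot(inherits(params, "cholesky_params"))
  mom <- as_twin_moments(data)
  mu <- rep(params$means, 2)
  v1 <- neg2ll_group(mu, build_expected_covariance(params, 1.0)$sigma, mom$groups$MZ)
  v2 <- neg2ll_group(mu, build_expected_covariance(params, 0.5)$sigma, mom$groups$DZ)
  v1 + v2
}
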
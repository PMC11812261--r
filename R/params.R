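#' Cholesky ACE path parameters
#'
#' Container for a trivariate Cholesky ACE parameterization: three 3 x 3
#' lower-triangular path matrices (`a`, `c`, `e`) whose outer products give
#' the additive-genetic, shared-environmental and nonshared-environmental
#' covariance components `A = a a'`, `C = c c'`, `E = e e'`, plus one
#' phenotypic mean per wave. Row `w` of each path matrix holds the loadings
#' of wave `w` on the latent factors originating at waves `1..w`; the
#' diagonal entries are the wave-unique paths and the sub-diagonal entries
#' the carry-over paths.
#'
#' By convention the diagonal paths are non-negative; columns with a
#' negative diagonal are sign-flipped (the likelihood is invariant to
#' column signs, so this only fixes reporting).
#'
#' @param a,c,e 3 x 3 lower-triangular matrices, or length-6 vectors in
#'   column-major lower-triangle order (11, 21, 31, 22, 32, 33).
#' @param means Numeric vector of 3 wave means.
#' @param normalize_signs Flip columns whose diagonal entry is negative.
#' @return An object of class `cholesky_params`.
#' @export
cholesky_params <- function(a, c, e, means = c(0, 0, 0), normalize_signs = TRUE) {
  as_lower <- function(m, nm) {
    if (is.vector(m) && length(m) == 6L) m <- vec_to_lower(m)
    m <- as.matrix(m)
    if (!all(dim(m) == c(3L, 3L))) stopf("`%s` must be 3 x 3 (or a length-6 vector)", nm)
    if (any(abs(m[upper.tri(m)]) > 0)) stopf("`%s` must be lower-triangular", nm)
    if (any(!is.finite(m[lower.tri(m, diag = TRUE)]))) stopf("`%s` has non-finite entries", nm)
    m
  }
  a <- as_lower(a, "a"); c <- as_lower(c, "c"); e <- as_lower(e, "e")
  if (length(means) != 3L || any(!is.finite(means))) stopf("`means` must be 3 finite values")
  if (normalize_signs) {
    for (k in 1:3) {
      if (a[k, k] < 0) a[, k] <- -a[, k]
      if (c[k, k] < 0) c[, k] <- -c[, k]
      if (e[k, k] < 0) e[, k] <- -e[, k]
    }
  }
  v <- rowSums(a^2 + c^2 + e^2)
  if (any(v <= 0)) stopf("implied total variance must be positive at every wave")
  structure(list(a = a, c = c, e = e, means = as.numeric(means)),
            class = "cholesky_params")
}

#' @export
print.cholesky_params <- function(x, digits = 3, ...) {
  cat("<cholesky_params> trivariate ACE path matrices\n")
  for (nm in c("a", "c", "e")) {
    cat(nm, ":\n", sep = "")
    print(round(x[[nm]], digits))
  }
  cat("means:", paste(round(x$means, digits), collapse = ", "), "\n")
  invisible(x)
}

#' Model-implied twin-pair covariance
#'
#' Assembles the 6 x 6 expected covariance matrix over the slots
#' (twin 1 x waves, twin 2 x waves) implied by Cholesky ACE paths. With
#' `A = a a'`, `C = c c'`, `E = e e'`, the within-twin blocks are
#' `A + C + E` and the cross-twin blocks `relatedness * A + C`, where
#' relatedness is 1 for monozygotic pairs (sharing all segregating genes)
#' and 0.5 for dizygotic pairs (sharing half, on average).
#'
#' @param params A [cholesky_params] object.
#' @param relatedness 1.0 (MZ) or 0.5 (DZ).
#' @return An object of class `expected_covariance`: list with the 6 x 6
#'   `sigma` (slot dimnames), the component matrices `A`, `C`, `E`, the
#'   6-vector `mu`, and `relatedness`.
#' @export
build_expected_covariance <- function(params, relatedness) {
  stopifnot(inherits(params, "cholesky_params"))
  if (!relatedness %in% c(1, 0.5)) stopf("`relatedness` must be 1.0 (MZ) or 0.5 (DZ)")
  A <- tcrossprod(params$a)
  C <- tcrossprod(params$c)
  E <- tcrossprod(params$e)
  within <- A + C + E
  cross <- relatedness * A + C
  sigma <- rbind(cbind(within, cross), cbind(cross, within))
  dimnames(sigma) <- list(slot_labels(), slot_labels())
  structure(list(sigma = sigma, A = A, C = C, E = E,
                 mu = rep(params$means, 2), relatedness = relatedness),
            class = "expected_covariance")
}

#' @export
print.expected_covariance <- function(x, digits = 3, ...) {
  cat(sprintf("<expected_covariance> relatedness = %g\n", x$relatedness))
  print(round(x$sigma, digits))
  invisible(x)
}

#' Standardized variance decomposition (path-diagram style)
#'
#' Standardizes a Cholesky ACE solution: at wave `w` the contribution of
#' the factor originating at wave `k <= w` through path matrix
#' `m in {a, c, e}` is `m[w,k]^2 / V_w`, with
#' `V_w = sum_m sum_k m[w,k]^2` the implied total variance. The nine
#' contributions at each wave sum to one. Totals per component (summing
#' origins) give the usual standardized A, C and E shares; the off-diagonal
#' cells are the carried-over shares displayed on longitudinal path
#' diagrams.
#'
#' @param x A [cholesky_params] object or a fitted ACE model
#'   (see [fit_model()]).
#' @param ... Unused.
#' @return An object of class `variance_decomposition`: list with `totals`
#'   (3 waves x A/C/E matrix), `origins` (list of 3 x 3 wave-by-origin
#'   share matrices for `a`, `c`, `e`) and `variance` (implied `V_w`).
#' @export
standardize <- function(x, ...) UseMethod("standardize")

#' @rdname standardize
#' @export
standardize.cholesky_params <- function(x, ...) {
  V <- rowSums(x$a^2 + x$c^2 + x$e^2)
  if (any(V <= 0)) stopf("zero implied variance; cannot standardize")
  shares <- lapply(list(a = x$a, c = x$c, e = x$e), function(m) m^2 / V)
  totals <- cbind(A = rowSums(shares$a), C = rowSums(shares$c), E = rowSums(shares$e))
  rownames(totals) <- wave_labels()
  for (nm in names(shares)) dimnames(shares[[nm]]) <- list(wave_labels(), wave_labels())
  structure(list(totals = totals, origins = shares, variance = V),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, digits = 3, ...) {
  cat("<variance_decomposition> standardized shares per wave\n")
  cat("totals (A/C/E):\n")
  print(round(x$totals, digits))
  cat("per-origin shares (rows: wave; cols: factor origin wave):\n")
  for (nm in c("a", "c", "e")) {
    cat(toupper(nm), "paths squared / V:\n")
    print(round(x$origins[[nm]], digits))
  }
  invisible(x)
}

#' @rdname standardize
#' @export
as.data.frame.variance_decomposition <- function(x, ...) {
  rows <- list()
  for (w in 1:3) for (k in 1:w) for (nm in c("a", "c", "e")) {
    rows[[length(rows) + 1L]] <- data.frame(
      wave = wave_labels()[w], component = toupper(nm),
      origin = wave_labels()[k], share = x$origins[[nm]][w, k],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Falconer's quick ACE estimates
#'
#' Algebraic variance-component estimates from a pair of twin
#' correlations: `A = 2 (r_MZ - r_DZ)`, `C = r_MZ - A`, `E = 1 - r_MZ`.
#' A 2:1 MZ:DZ correlation ratio thus yields a purely additive-genetic
#' solution, a 1:1 ratio a purely shared-environmental one. Raw algebraic
#' values are returned without truncation; a `clamped` view restricted to
#' `[0, 1]` is attached for convenience.
#'
#' @param r_mz,r_dz Monozygotic and dizygotic twin correlations.
#' @return An object of class `falconer_estimates` with elements `A`, `C`,
#'   `E` and `clamped`.
#' @examples
#' falconer_estimates(0.5, 0.25)   # pure additive case: A = 0.5, C = 0
#' falconer_estimates(0.97, 0.92)  # strong shared environment
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1) stopf("correlations must lie in [-1, 1]")
  A <- 2 * (r_mz - r_dz)
  C <- r_mz - A
  E <- 1 - r_mz
  raw <- c(A = A, C = C, E = E)
  structure(list(A = A, C = C, E = E,
                 clamped = pmin(pmax(raw, 0), 1)),
            class = "falconer_estimates")
}

#' @export
print.falconer_estimates <- function(x, digits = 3, ...) {
  cat(sprintf("Falconer estimates: A = %.*f, C = %.*f, E = %.*f\n",
              digits, x$A, digits, x$C, digits, x$E))
  invisible(x)
}
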
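#' Published Gemini twin correlations for emotional overeating
#'
#' Twin correlation matrices for emotional overeating (EOE) reported by the
#' UK Gemini twin birth cohort across three waves (16 months, 5 years,
#' 12 years): per-zygosity 6 x 6 double-entry correlation matrices over the
#' (twin x wave) slots, baseline pair counts, per-wave individual counts
#' and raw-score summary statistics. These published estimates serve as
#' complete-data sufficient statistics for re-fitting the longitudinal ACE
#' Cholesky model when the raw cohort data are unavailable (see
#' [twin_moments()]), and as calibration targets for the synthetic cohort
#' generator ([gemini_like_config()]).
#'
#' @return A list with elements
#'   \describe{
#'     \item{mz, dz}{6 x 6 correlation matrices (slot dimnames).}
#'     \item{n_pairs}{Baseline pair counts, `c(MZ = 749, DZ = 1616)`.}
#'     \item{wave_n}{Individuals with an EOE score per wave
#'       (3784, 2064, 964; 4804 at baseline).}
#'     \item{score_means, score_sds}{Raw EOE subscale means and SDs per
#'       wave.}
#'     \item{ages}{Mean (and SD) age per wave: months at 16 months, years
#'       later.}
#'   }
#' @export
published_eoe_correlations <- function() {
  within <- matrix(c(1, .28, .22,
                     .28, 1, .43,
                     .22, .43, 1), 3, 3, byrow = TRUE)
  cross_mz <- matrix(c(.97, .28, .22,
                       .28, .98, .43,
                       .22, .43, .95), 3, 3, byrow = TRUE)
  cross_dz <- matrix(c(.92, .28, .23,
                       .28, .93, .40,
                       .23, .40, .73), 3, 3, byrow = TRUE)
  assemble <- function(cr) {
    m <- rbind(cbind(within, cr), cbind(t(cr), within))
    dimnames(m) <- list(slot_labels(), slot_labels())
    symm(m)
  }
  list(mz = assemble(cross_mz),
       dz = assemble(cross_dz),
       n_pairs = c(MZ = 749, DZ = 1616),
       wave_n = c(`baseline` = 4804, `16m` = 3784, `5y` = 2064, `12y` = 964),
       score_means = c(`16m` = 1.64, `5y` = 1.57, `12y` = 1.75),
       score_sds = c(`16m` = 0.59, `5y` = 0.51, `12y` = 0.61),
       ages = list(mean = c(`16m` = 15.8, `5y` = 5.15, `12y` = 12.69),
                   sd = c(`16m` = 0.1, `5y` = 0.13, `12y` = 0.43)))
}

#' Fit the ACE Cholesky model to the published correlation matrices
#'
#' Convenience wrapper: treats the published per-zygosity EOE correlation
#' matrices as complete-data sample covariances (unit variances), weights
#' the two groups by the published baseline pair counts, and fits the
#' 18-path ACE Cholesky by two-group maximum likelihood.
#'
#' @param starts,seed,maxit Passed to [fit_model()].
#' @return A `twin_fit` (see [fit_model()]).
#' @export
fit_published_ace <- function(starts = 5L, seed = 1L, maxit = 2000L) {
  pub <- published_eoe_correlations()
  mom <- twin_moments(pub$mz, pub$dz, pub$n_pairs[["MZ"]], pub$n_pairs[["DZ"]])
  fit_model(mom, "ace", starts = starts, seed = seed, maxit = maxit)
}
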
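#' Residualize EOE scores on sex and age
#'
#' Regresses the EOE score at each wave on sex (binary indicator) and age at
#' that wave, pooling the two twins of every pair, and replaces scores by
#' the ordinary-least-squares residuals. This is the standard preparation
#' step in twin modelling: age is identical for co-twins and sex is shared
#' by all same-sex pairs, so leaving these covariates in would inflate
#' shared-environment estimates.
#'
#' Each wave is fitted separately over all individual twins with a complete
#' (score, sex, age) triple at that wave; missing scores stay missing. Age
#' units are whatever the file records per wave (months at 16 months, years
#' later) -- regressions never mix waves, so units never mix.
#'
#' @param x A [twin_pairs] object with raw scores.
#' @return A [twin_pairs] object with `residualized = TRUE`; per wave, the
#'   residuals have mean (numerically) zero and are orthogonal to sex and
#'   age.
#' @export
residualize_scores <- function(x) {
  stopifnot(inherits(x, "twin_pairs"))
  if (x$residualized) stopf("dataset is already residualized")
  d <- x$data
  for (w in seq_along(x$waves)) {
    wave <- x$waves[w]
    age <- d[[paste0("age_", wave)]]
    y <- c(d[[sprintf("eoe_t1_%s", wave)]], d[[sprintf("eoe_t2_%s", wave)]])
    male <- as.numeric(c(d$sex_t1 == "M", d$sex_t2 == "M"))
    agev <- c(age, age)
    ok <- !is.na(y) & !is.na(male) & !is.na(agev)
    if (sum(ok) < 3L) {
      stopf("wave %s has %d complete observation(s); need at least 3 for the sex/age regression",
            wave, sum(ok))
    }
    X <- cbind(1, male[ok], agev[ok])
    res <- stats::lm.fit(X, y[ok])$residuals
    y[ok] <- res
    n <- nrow(d)
    d[[sprintf("eoe_t1_%s", wave)]] <- y[seq_len(n)]
    d[[sprintf("eoe_t2_%s", wave)]] <- y[n + seq_len(n)]
  }
  out <- x
  out$data <- d
  out$residualized <- TRUE
  out
}
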
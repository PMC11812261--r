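# Synthetic twin-cohort generator.

#' Likert discretization settings
#'
#' Builds the item-threshold layout used to turn latent trait values into
#' CEBQ-style item responses. Each wave has `n_items` items; item `j`
#' shares four equally spaced cutpoints (`base + spacing * 0:3`) shifted by
#' an item-specific stagger offset, so that the item average approximates a
#' fine monotone staircase of the latent trait. A response is
#' `1 + #(cutpoints below the latent value)`, i.e. an integer in 1..5, and
#' the wave score is the item mean (CEBQ scoring).
#'
#' @param base Numeric vector (one per wave): location of the first
#'   cutpoint on the latent scale.
#' @param spacing Numeric vector (one per wave): distance between
#'   consecutive cutpoints of an item.
#' @param stagger Numeric vector (one per wave): spread of the
#'   item-specific offsets.
#' @param n_items Items per wave (3 for the toddler scale, 4 otherwise).
#' @param item_noise_sd Standard deviation of optional item-specific
#'   (twin-specific) noise added to the latent value before thresholding.
#' @return A list with `n_items` and per-wave threshold matrices
#'   (`n_items x 4`), suitable for the `likert` field of
#'   [simulation_config()].
#' @export
likert_settings <- function(base, spacing, stagger = rep(0.4, 3),
                            n_items = c(3L, 4L, 4L), item_noise_sd = 0) {
  stopifnot(length(base) == 3L, length(spacing) == 3L, length(stagger) == 3L,
            length(n_items) == 3L, all(spacing > 0))
  thresholds <- lapply(1:3, function(w) {
    k <- n_items[w]
    offs <- (seq_len(k) - (k + 1) / 2) * stagger[w]
    t(vapply(offs, function(o) base[w] + o + spacing[w] * 0:3, numeric(4)))
  })
  for (w in 1:3) {
    if (any(diff(t(thresholds[[w]])) <= 0)) stopf("thresholds must be strictly increasing")
  }
  list(n_items = as.integer(n_items), thresholds = thresholds,
       item_noise_sd = item_noise_sd)
}

#' Configuration of a synthetic twin cohort
#'
#' Bundles everything [simulate_cohort()] needs: the generating Cholesky
#' ACE paths, group sizes, per-wave retention probabilities
#' (pair-level, missing-completely-at-random questionnaire non-return),
#' optional Likert discretization settings, and per-wave age distributions
#' and covariate effects (applied on the latent scale, centred so they do
#' not shift wave means).
#'
#' @param params A [cholesky_params] object: the generating paths.
#' @param n_mz,n_dz Numbers of monozygotic / dizygotic pairs.
#' @param wave_retention Probabilities in `(0, 1]` that a pair returns the
#'   questionnaire at each wave (both twins observed or missing together).
#' @param likert `NULL` for continuous latent scores, or settings from
#'   [likert_settings()].
#' @param age_means,age_sds Per-wave age distributions (months at the
#'   first wave, years later; ages are shared by co-twins).
#' @param sex_effect Per-wave additive effect of sex on the latent score
#'   (male minus female difference).
#' @param age_effect Per-wave additive effect of (centred) age per unit.
#' @param seed Default seed for [simulate_cohort()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params, n_mz, n_dz,
                              wave_retention = c(1, 1, 1),
                              likert = NULL,
                              age_means = c(15.8, 5.15, 12.69),
                              age_sds = c(0.1, 0.13, 0.43),
                              sex_effect = c(0, 0, 0),
                              age_effect = c(0, 0, 0),
                              seed = NULL) {
  stopifnot(inherits(params, "cholesky_params"))
  if (n_mz < 1 || n_dz < 1) stopf("group sizes must be positive")
  if (length(wave_retention) != 3L || any(wave_retention <= 0 | wave_retention > 1)) {
    stopf("`wave_retention` must be 3 probabilities in (0, 1]")
  }
  if (!is.null(likert)) {
    stopifnot(is.list(likert), length(likert$thresholds) == 3L)
    for (w in 1:3) {
      if (any(diff(t(likert$thresholds[[w]])) <= 0)) {
        stopf("likert thresholds must be strictly increasing within each item")
      }
    }
  }
  structure(list(params = params, n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 wave_retention = wave_retention, likert = likert,
                 age_means = age_means, age_sds = age_sds,
                 sex_effect = sex_effect, age_effect = age_effect, seed = seed),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d MZ + %d DZ pairs; retention %s; %s scores\n",
              x$n_mz, x$n_dz, paste(round(x$wave_retention, 3), collapse = "/"),
              if (is.null(x$likert)) "latent continuous" else "Likert-discretized"))
  invisible(x)
}

#' @noRd
mvn_sqrt <- function(sigma) {
  e <- eigen(symm(sigma), symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    stopf("expected covariance is not positive semi-definite")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)))
}

#' Simulate a twin-pair cohort
#'
#' Draws latent trivariate scores for both members of each pair from the
#' zygosity-appropriate expected covariance (relatedness 1.0 for MZ, 0.5
#' for DZ pairs), adds centred sex and age effects, optionally discretizes
#' to per-item Likert responses which are averaged CEBQ-style, and applies
#' pair-level wave retention (both twins missing together, independently
#' across waves and pairs). Pairs left with no observed wave are excluded,
#' as in cohort inclusion rules. Fully reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [twin_pairs] dataset.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) stopf("a seed is required (in `config$seed` or the `seed` argument)")
  withr::with_seed(as.integer(seed), {
    blocks <- lapply(c(MZ = 1.0, DZ = 0.5), function(rel) {
      n <- if (rel == 1.0) config$n_mz else config$n_dz
      zyg <- if (rel == 1.0) "MZ" else "DZ"
      sig <- build_expected_covariance(config$params, rel)
      L <- mvn_sqrt(sig$sigma)
      Z <- matrix(stats::rnorm(n * 6L), n, 6L) %*% t(L)
      Z <- sweep(Z, 2L, sig$mu, `+`)

      ages <- vapply(1:3, function(w) {
        stats::rnorm(n, config$age_means[w], config$age_sds[w])
      }, numeric(n))
      if (zyg == "MZ") {
        sex1 <- sex2 <- sample(c("M", "F"), n, replace = TRUE)
      } else {
        sex1 <- sample(c("M", "F"), n, replace = TRUE)
        sex2 <- sample(c("M", "F"), n, replace = TRUE)
      }
      for (w in 1:3) {
        adj <- config$age_effect[w] * (ages[, w] - config$age_means[w])
        Z[, w] <- Z[, w] + adj + config$sex_effect[w] * ((sex1 == "M") - 0.5)
        Z[, w + 3L] <- Z[, w + 3L] + adj + config$sex_effect[w] * ((sex2 == "M") - 0.5)
      }

      if (!is.null(config$likert)) {
        lik <- config$likert
        score <- matrix(NA_real_, n, 6L)
        for (s in 1:6) {
          w <- if (s > 3L) s - 3L else s
          thr <- lik$thresholds[[w]]
          k <- nrow(thr)
          acc <- numeric(n)
          for (j in seq_len(k)) {
            lat <- Z[, s]
            if ((lik$item_noise_sd %||% 0) > 0) {
              lat <- lat + stats::rnorm(n, 0, lik$item_noise_sd)
            }
            acc <- acc + 1 + findInterval(lat, thr[j, ])
          }
          score[, s] <- acc / k
        }
      } else {
        score <- Z
      }

      present <- vapply(1:3, function(w) {
        stats::runif(n) < config$wave_retention[w]
      }, logical(n))
      for (w in 1:3) {
        score[!present[, w], c(w, w + 3L)] <- NA_real_
        ages[!present[, w], w] <- NA_real_
      }

      d <- data.frame(pair_id = sprintf("%s%05d", tolower(zyg), seq_len(n)),
                      zygosity = zyg, sex_t1 = sex1, sex_t2 = sex2,
                      stringsAsFactors = FALSE)
      d[age_columns()] <- as.data.frame(ages)
      d[score_columns()] <- as.data.frame(score)
      d
    })
    twin_pairs(rbind(blocks$MZ, blocks$DZ), residualized = FALSE,
               range_check = !is.null(config$likert))
  })
}

# Generating paths calibrated so that the simulated cohort's double-entry
# score correlations (after Likert discretization) match the published
# Gemini EOE correlation matrices. Calibrated once by the iterative script
# in data-raw/; see the methods vignette.
#' @noRd
gemini_params <- function() {
  cholesky_params(
    a = c(0.28092, -0.00433, -0.08122, 0.28175, 0.21036, 0.58924),
    c = c(0.95297, 0.34367, 0.28667, 0.89105, 0.35743, 0.59826),
    e = c(0.11371, 0.00039, -0.00138, 0.09213, -0.00057, 0.18497),
    means = c(0, 0, 0))
}

#' Gemini-like simulation configuration
#'
#' A packaged default [simulation_config()] emulating the structure of the
#' Gemini twin cohort's emotional-overeating data: 749 MZ and 1653 DZ
#' pairs (2402 pairs, ~31% monozygotic), wave retention reproducing the
#' published per-wave sample sizes (3784, 2064 and 964 individuals out of
#' 4804) in expectation, Likert discretization calibrated so wave score
#' means fall near the published 1.64 / 1.57 / 1.75, and generating paths
#' calibrated so the simulated cohort's twin correlation matrices match
#' the published ones (see [published_eoe_correlations()]).
#'
#' @param n_mz,n_dz Group sizes (defaults as above).
#' @param likert `TRUE` for calibrated Likert scores (default), `FALSE`
#'   for continuous latent scores.
#' @param seed Default seed carried in the config.
#' @return A [simulation_config()].
#' @export
gemini_like_config <- function(n_mz = 749L, n_dz = 1653L, likert = TRUE,
                               seed = 2007L) {
  pub <- published_eoe_correlations()
  lik <- if (likert) {
    likert_settings(base = c(0.1495, 0.2881, 0.0190),
                    spacing = c(0.9, 0.9, 0.9),
                    stagger = c(0.4, 0.4, 0.4))
  } else NULL
  simulation_config(
    params = gemini_params(),
    n_mz = n_mz, n_dz = n_dz,
    wave_retention = unname(pub$wave_n[c("16m", "5y", "12y")] / pub$wave_n[["baseline"]]),
    likert = lik,
    age_means = unname(pub$ages$mean), age_sds = unname(pub$ages$sd),
    sex_effect = c(0.05, 0.05, 0.05),
    age_effect = c(0.10, 0.10, 0.05),
    seed = seed)
}
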
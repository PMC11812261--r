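# Calibration of the Gemini-like generator defaults.
#
# The generator discretizes latent trait values to 5-point Likert items with
# a strong floor (wave means ~1.6 on a 1-5 scale), which attenuates Pearson
# correlations of the resulting scores relative to the latent scale. The
# published twin correlations are properties of the *observed* scores, so
# the generating paths are calibrated by a fixed-point iteration: fit paths
# to latent target matrices, simulate a large cohort, measure the observed
# double-entry correlations, and shift the latent targets by the residual
# against the published matrices. Item thresholds are simultaneously
# adjusted so that wave score means match the published 1.64/1.57/1.75.
#
# Run from the package root after installing the package:
#   Rscript data-raw/calibrate_gemini.R
# The resulting constants are frozen into gemini_params() and
# gemini_like_config() in R/simulate.R.

library(twinace)

pub <- published_eoe_correlations()
target_means <- unname(pub$score_means)

n_cal <- 50000L          # pairs per zygosity group per iteration
base <- c(0.147, 0.300, 0.006)
spacing <- c(0.9, 0.9, 0.9)
stagger <- c(0.4, 0.4, 0.4)

T_mz <- pub$mz
T_dz <- pub$dz

observed_matrix <- function(Y) {
  # double-entry 6x6 correlation matrix (swap twin blocks and pool)
  P <- c(4:6, 1:3)
  Yd <- rbind(Y, Y[, P])
  stats::cor(Yd, use = "pairwise.complete.obs")
}

fit_to_targets <- function(T_mz, T_dz) {
  mom <- twin_moments(T_mz, T_dz, pub$n_pairs[["MZ"]], pub$n_pairs[["DZ"]])
  fit_model(mom, "ace", starts = 5, seed = 1)
}

for (it in 1:6) {
  fit <- fit_to_targets(T_mz, T_dz)
  cfg <- simulation_config(
    params = fit$params, n_mz = n_cal, n_dz = n_cal,
    likert = likert_settings(base, spacing, stagger),
    sex_effect = c(0.05, 0.05, 0.05), age_effect = c(0.10, 0.10, 0.05),
    seed = 1000L + it)
  d <- simulate_cohort(cfg)
  Y <- twinace:::score_matrix(d)
  zyg <- d$data$zygosity
  O_mz <- observed_matrix(Y[zyg == "MZ", ])
  O_dz <- observed_matrix(Y[zyg == "DZ", ])
  means <- (colMeans(Y, na.rm = TRUE)[1:3] + colMeans(Y, na.rm = TRUE)[4:6]) / 2

  dev_mz <- pub$mz - O_mz
  dev_dz <- pub$dz - O_dz
  cat(sprintf("iter %d: max |dev| MZ %.4f DZ %.4f; means %s\n",
              it, max(abs(dev_mz)), max(abs(dev_dz)),
              paste(sprintf("%.3f", means), collapse = "/")))

  T_mz <- pmin(T_mz + dev_mz, 0.997); diag(T_mz) <- 1
  T_dz <- pmin(T_dz + dev_dz, 0.997); diag(T_dz) <- 1
  base <- base + (means - target_means) * 1.4
}

fit <- fit_to_targets(T_mz, T_dz)
cat("\nCalibrated paths (freeze into gemini_params()):\n")
print(fit$params$a, digits = 6)
print(fit$params$c, digits = 6)
print(fit$params$e, digits = 6)
cat("\nCalibrated likert base (freeze into gemini_like_config()):\n")
print(round(base, 4))
cat("\ndput for code:\n")
dput(round(twinace:::lower_to_vec(fit$params$a), 5))
dput(round(twinace:::lower_to_vec(fit$params$c), 5))
dput(round(twinace:::lower_to_vec(fit$params$e), 5))
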
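# Two-group model fitting: saturated baselines and the ACE Cholesky.

#' @noRd
normalize_kind <- function(model) {
  aliases <- c(saturated = "saturated",
               sub1a = "sub1a", saturated_equal_order = "sub1a",
               sub1b = "sub1b", saturated_equal_order_zygosity = "sub1b",
               ace = "ace", ace_cholesky = "ace")
  if (length(model) != 1L || !model %in% names(aliases)) {
    stopf("unknown model kind \"%s\"; use one of: saturated, sub1a, sub1b, ace",
          paste(model, collapse = ","))
  }
  unname(aliases[model])
}

#' Free-parameter counts of the supported models
#'
#' Counts of freely estimated parameters for the two-group three-wave
#' models: the fully saturated model (per group: 6 means and 21 covariance
#' elements; 54 in total), the order-constrained saturated model (means and
#' variances equated across twin order within group, covariances free; 42),
#' the order- and zygosity-constrained model (means and variances shared
#' across order and groups, covariances free per group; 36 under this
#' implementation's constraint set), and the ACE Cholesky (18 paths plus 3
#' wave means; 21).
#'
#' @param model Model kind: `"saturated"`, `"sub1a"`
#'   (`"saturated_equal_order"`), `"sub1b"`
#'   (`"saturated_equal_order_zygosity"`) or `"ace"` (`"ace_cholesky"`).
#' @param n_waves Number of waves; only 3 is supported.
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(model, n_waves = 3L) {
  kind <- normalize_kind(model)
  if (n_waves != 3L) stopf("only the three-wave design is supported")
  switch(kind,
         saturated = 2L * (6L + 21L),
         sub1a = 2L * (3L + 3L + 15L),
         sub1b = 3L + 3L + 2L * 15L,
         ace = 18L + 3L)
}

# Pooled (pairwise-complete) per-group moments, used for starting values.
#' @noRd
pooled_moments <- function(patterns) {
  mu_num <- mu_den <- numeric(6)
  for (p in patterns) {
    mu_num[p$idx] <- mu_num[p$idx] + p$n * p$mean
    mu_den[p$idx] <- mu_den[p$idx] + p$n
  }
  mu <- ifelse(mu_den > 0, mu_num / pmax(mu_den, 1), 0)
  C_num <- C_den <- matrix(0, 6, 6)
  for (p in patterns) {
    d <- p$mean - mu[p$idx]
    contrib <- p$S + outer(d, d)
    C_num[p$idx, p$idx] <- C_num[p$idx, p$idx] + p$n * contrib
    C_den[p$idx, p$idx] <- C_den[p$idx, p$idx] + p$n
  }
  S <- ifelse(C_den > 0, C_num / pmax(C_den, 1), 0)
  diag(S)[diag(C_den) == 0] <- 1
  list(mu = mu, S = symm(S))
}

# Twin-order swap permutation of the 6 slots.
#' @noRd
swap_perm <- function() c(4:6, 1:3)

#' @noRd
order_symmetrized <- function(S) {
  P <- swap_perm()
  symm((S + S[P, P]) / 2)
}

# --- model parameterizations -------------------------------------------------

# Each builder returns: npar, names, start(mom), unpack(theta) giving
# per-group mu/sigma (and, for the ACE, the cholesky_params).

#' @noRd
model_builder <- function(kind) {
  off_idx <- which(lower.tri(diag(6)))                   # 15 off-diagonal cells
  wave_of_slot <- c(1:3, 1:3)

  sigma_from_vc <- function(logv, covs) {
    m <- matrix(0, 6, 6)
    m[off_idx] <- covs
    m <- m + t(m)
    diag(m) <- exp(pmin(logv, 30))[wave_of_slot]  # cap guards optimizer excursions
    m
  }
  # Start covariances as a correlation shape rescaled to the start
  # variances, shrunk toward the identity so the start is always PD even
  # when pairwise-complete moments are not.
  safe_covs <- function(S, v) {
    R <- stats::cov2cor(psd_floor(order_symmetrized(S), 1e-4))
    R <- 0.9 * R + 0.1 * diag(6)
    sd6 <- sqrt(v)[wave_of_slot]
    (outer(sd6, sd6) * R)[off_idx]
  }
  vc_start <- function(S, v = NULL) {
    Ssym <- order_symmetrized(S)
    if (is.null(v)) v <- pmax((diag(Ssym)[1:3] + diag(Ssym)[4:6]) / 2, 1e-4)
    list(logv = log(v), covs = safe_covs(S, v))
  }

  if (kind == "saturated") {
    list(
      npar = 54L,
      names = c(paste0("mz_mu", 1:6), paste0("mz_", lower_names("L", 6)),
                paste0("dz_mu", 1:6), paste0("dz_", lower_names("L", 6))),
      start = function(mom) {
        st <- function(g) {
          pm <- pooled_moments(mom$groups[[g]])
          L <- t(chol(psd_floor(pm$S, 1e-3)))
          c(pm$mu, lower_to_vec(L))
        }
        c(st("MZ"), st("DZ"))
      },
      unpack = function(theta) {
        grp <- function(off) {
          mu <- theta[off + 1:6]
          L <- vec_to_lower(theta[off + 6 + 1:21], 6L)
          list(mu = mu, sigma = tcrossprod(L))
        }
        list(MZ = grp(0L), DZ = grp(27L), params = NULL)
      })
  } else if (kind == "sub1a") {
    list(
      npar = 42L,
      names = c(paste0("mz_mu_w", 1:3), paste0("mz_logv_w", 1:3), paste0("mz_cov", 1:15),
                paste0("dz_mu_w", 1:3), paste0("dz_logv_w", 1:3), paste0("dz_cov", 1:15)),
      start = function(mom) {
        st <- function(g) {
          pm <- pooled_moments(mom$groups[[g]])
          vs <- vc_start(pm$S)
          mu3 <- (pm$mu[1:3] + pm$mu[4:6]) / 2
          c(mu3, vs$logv, vs$covs)
        }
        c(st("MZ"), st("DZ"))
      },
      unpack = function(theta) {
        grp <- function(off) {
          mu <- rep(theta[off + 1:3], 2)
          list(mu = mu, sigma = sigma_from_vc(theta[off + 3 + 1:3], theta[off + 6 + 1:15]))
        }
        list(MZ = grp(0L), DZ = grp(21L), params = NULL)
      })
  } else if (kind == "sub1b") {
    list(
      npar = 36L,
      names = c(paste0("mu_w", 1:3), paste0("logv_w", 1:3),
                paste0("mz_cov", 1:15), paste0("dz_cov", 1:15)),
      start = function(mom) {
        pm_mz <- pooled_moments(mom$groups$MZ)
        pm_dz <- pooled_moments(mom$groups$DZ)
        w <- mom$n_pairs / sum(mom$n_pairs)
        mu3 <- w[1] * (pm_mz$mu[1:3] + pm_mz$mu[4:6]) / 2 +
               w[2] * (pm_dz$mu[1:3] + pm_dz$mu[4:6]) / 2
        v_shared <- pmax(w[1] * exp(vc_start(pm_mz$S)$logv) +
                           w[2] * exp(vc_start(pm_dz$S)$logv), 1e-4)
        v_mz <- vc_start(pm_mz$S, v_shared); v_dz <- vc_start(pm_dz$S, v_shared)
        c(mu3, log(v_shared), v_mz$covs, v_dz$covs)
      },
      unpack = function(theta) {
        mu <- rep(theta[1:3], 2)
        logv <- theta[3 + 1:3]
        list(MZ = list(mu = mu, sigma = sigma_from_vc(logv, theta[6 + 1:15])),
             DZ = list(mu = mu, sigma = sigma_from_vc(logv, theta[21 + 1:15])),
             params = NULL)
      })
  } else {  # ace
    list(
      npar = 21L,
      names = c(lower_names("a"), lower_names("c"), lower_names("e"),
                paste0("mu_w", 1:3)),
      start = function(mom) {
        pm_mz <- pooled_moments(mom$groups$MZ)
        pm_dz <- pooled_moments(mom$groups$DZ)
        S_mz <- order_symmetrized(pm_mz$S); S_dz <- order_symmetrized(pm_dz$S)
        W <- (S_mz[1:3, 1:3] + S_dz[1:3, 1:3]) / 2
        X_mz <- symm(S_mz[1:3, 4:6]); X_dz <- symm(S_dz[1:3, 4:6])
        A0 <- psd_floor(2 * (X_mz - X_dz), 1e-2)
        C0 <- psd_floor(2 * X_dz - X_mz, 1e-2)
        E0 <- psd_floor(W - A0 - C0, 1e-2)
        w <- mom$n_pairs / sum(mom$n_pairs)
        mu3 <- w[1] * (pm_mz$mu[1:3] + pm_mz$mu[4:6]) / 2 +
               w[2] * (pm_dz$mu[1:3] + pm_dz$mu[4:6]) / 2
        c(lower_to_vec(t(chol(A0))), lower_to_vec(t(chol(C0))),
          lower_to_vec(t(chol(E0))), mu3)
      },
      unpack = function(theta) {
        p <- theta_to_params(theta)
        list(MZ = list(mu = rep(p$means, 2),
                       sigma = build_expected_covariance(p, 1.0)$sigma),
             DZ = list(mu = rep(p$means, 2),
                       sigma = build_expected_covariance(p, 0.5)$sigma),
             params = p)
      })
  }
}

#' @noRd
theta_to_params <- function(theta, normalize_signs = FALSE) {
  cholesky_params(vec_to_lower(theta[1:6]), vec_to_lower(theta[7:12]),
                  vec_to_lower(theta[13:18]), means = theta[19:21],
                  normalize_signs = normalize_signs)
}

#' @noRd
model_objective <- function(kind, mom) {
  builder <- model_builder(kind)
  fn <- function(theta) {
    g <- builder$unpack(theta)
    neg2ll_group(g$MZ$mu, g$MZ$sigma, mom$groups$MZ) +
      neg2ll_group(g$DZ$mu, g$DZ$sigma, mom$groups$DZ)
  }
  list(builder = builder, fn = fn)
}

#' @noRd
run_bfgs <- function(fn, theta0, maxit = 2000L, reltol = 1e-10) {
  ctl <- list(maxit = maxit, reltol = reltol, ndeps = rep(1e-6, length(theta0)))
  o1 <- stats::optim(theta0, fn, method = "BFGS", control = ctl)
  # restart once from the optimum: cheap insurance for finite-difference BFGS
  o2 <- stats::optim(o1$par, fn, method = "BFGS", control = ctl)
  if (o2$value <= o1$value) o2 else o1
}

#' Fit a twin model by full-information maximum likelihood
#'
#' Numerically maximizes the FIML likelihood of one of the supported
#' two-group models:
#'
#' * `"saturated"` -- unconstrained per-group means and covariances (the
#'   baseline for assumption testing),
#' * `"sub1a"` -- means and variances equated across twin order within
#'   each zygosity group,
#' * `"sub1b"` -- means and variances additionally equated across
#'   zygosity groups,
#' * `"ace"` -- the trivariate Cholesky ACE model: shared path matrices
#'   across groups with cross-twin relatedness 1.0 (MZ) / 0.5 (DZ).
#'
#' Covariance structures are parameterized to keep optimization
#' unconstrained (Cholesky factors for the saturated and ACE models;
#' log-variances for the constrained baselines); non-positive-definite
#' proposals are handled by a graded penalty. The ACE model is fitted with
#' multiple starts (a moment-based start plus random perturbations) and
#' reported with the sign convention that diagonal paths are non-negative.
#'
#' @param data A [twin_pairs] dataset (both zygosity groups present) or a
#'   [twin_moments] summary object.
#' @param model Model kind; see above (aliases
#'   `"saturated_equal_order"`, `"saturated_equal_order_zygosity"`,
#'   `"ace_cholesky"` are accepted).
#' @param starts Number of optimization starts (default 5 for the ACE
#'   model, 1 otherwise).
#' @param seed Integer seed controlling the random restarts (fits are
#'   deterministic given `seed`).
#' @param maxit Maximum BFGS iterations per start.
#' @return An object of class `twin_fit` with elements `model`,
#'   `estimates` (named parameter vector), `params` (a [cholesky_params]
#'   for the ACE model), `groups` (model-implied per-group mean and
#'   covariance), `minus2ll`, `ep`, `df`, `aic`, `nobs`, `n_pairs` and
#'   `converged`. `df` is the number of non-missing observations minus
#'   `ep`; `aic = minus2ll + 2 * ep`.
#' @export
fit_model <- function(data, model = c("ace", "saturated", "sub1a", "sub1b"),
                      starts = NULL, seed = 1L, maxit = 2000L) {
  kind <- normalize_kind(match.arg(model,
    c("ace", "saturated", "sub1a", "sub1b",
      "saturated_equal_order", "saturated_equal_order_zygosity", "ace_cholesky")))
  mom <- as_twin_moments(data)
  if (!length(mom$groups$MZ) || !length(mom$groups$DZ)) {
    stopf("both zygosity groups must be present to fit a twin model")
  }
  ob <- model_objective(kind, mom)
  starts <- starts %||% if (kind == "ace") 5L else 1L
  theta0 <- ob$builder$start(mom)
  theta_starts <- list(theta0)
  if (starts > 1L) {
    jitters <- withr::with_seed(seed, {
      lapply(seq_len(starts - 1L), function(i) stats::rnorm(length(theta0), 0, 0.15))
    })
    for (j in jitters) theta_starts[[length(theta_starts) + 1L]] <- theta0 + j
  }
  best <- NULL
  for (th in theta_starts) {
    o <- run_bfgs(ob$fn, th, maxit = maxit)
    if (is.null(best) || o$value < best$value) best <- o
  }
  converged <- best$convergence == 0 && best$value < 1e9
  theta <- best$par
  names(theta) <- ob$builder$names
  g <- ob$builder$unpack(theta)
  params <- if (kind == "ace") theta_to_params(best$par, normalize_signs = TRUE) else NULL
  ep <- count_free_parameters(kind)
  structure(list(model = kind, estimates = theta, theta = best$par,
                 params = params,
                 groups = list(MZ = g$MZ, DZ = g$DZ),
                 minus2ll = best$value, ep = ep, df = mom$nobs - ep,
                 aic = best$value + 2 * ep,
                 nobs = mom$nobs, n_pairs = mom$n_pairs,
                 converged = converged, starts = length(theta_starts),
                 seed = seed, counts = best$counts),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<twin_fit> %s model: -2LL = %.3f, AIC = %.3f, ep = %d, df = %d%s\n",
              x$model, x$minus2ll, x$aic, x$ep, x$df,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$params)) {
    print(x$params, digits = digits)
    cat("standardized totals:\n")
    print(round(standardize(x$params)$totals, digits))
  }
  invisible(x)
}

#' @rdname standardize
#' @export
standardize.twin_fit <- function(x, ...) {
  if (is.null(x$params)) stopf("standardize() needs an ACE fit")
  standardize(x$params)
}

#' Akaike information criterion from -2LL and parameter count
#'
#' @param minus2ll Minus twice the log likelihood.
#' @param ep Number of estimated parameters.
#' @return `minus2ll + 2 * ep`.
#' @export
aic_value <- function(minus2ll, ep) minus2ll + 2 * ep

#' Likelihood-ratio comparison of nested twin models
#'
#' Computes the chi-square difference test between a full model and a
#' nested (more constrained) model fitted to the same data: the difference
#' in -2 log likelihood is referred to a chi-square distribution with
#' degrees of freedom equal to the difference in estimated parameters. The
#' nested model is preferred when the test is non-significant (no
#' significant loss of fit) or when its AIC is lower.
#'
#' @param full,nested Converged [fit_model()] results, with
#'   `nested$ep < full$ep`.
#' @return An object of class `model_comparison` with `delta_chi2`,
#'   `delta_df`, `p_value`, `delta_aic`.
#' @export
compare_models <- function(full, nested) {
  stopifnot(inherits(full, "twin_fit"), inherits(nested, "twin_fit"))
  if (!full$converged || !nested$converged) {
    stopf("compare_models() refuses unconverged fits")
  }
  if (nested$ep >= full$ep) stopf("`nested` must have fewer parameters than `full`")
  delta <- nested$minus2ll - full$minus2ll
  if (delta < -1e-6) {
    stopf("nested model fits better than full by %.3g: optimizer failure", -delta)
  }
  delta <- max(delta, 0)
  ddf <- full$ep - nested$ep
  structure(list(full = full$model, nested = nested$model,
                 delta_chi2 = delta, delta_df = ddf,
                 p_value = stats::pchisq(delta, ddf, lower.tail = FALSE),
                 delta_aic = nested$aic - full$aic),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: delta chi2 = %.3f (df = %d), p = %.3g, delta AIC = %.3f\n",
              x$nested, x$full, x$delta_chi2, x$delta_df, x$p_value, x$delta_aic))
  invisible(x)
}
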
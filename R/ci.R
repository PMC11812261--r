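# Likelihood-based and bootstrap confidence intervals.

#' Profile-likelihood interval for a scalar target
#'
#' Generic profile-likelihood engine: given a -2 log likelihood function,
#' its minimizer, and a scalar target (a parameter index or a function of
#' the parameter vector), finds the two values of the target at which the
#' profiled -2LL rises by the chi-square(1) quantile of `level` (3.841 at
#' 95%) above its minimum.
#'
#' For an index target the profile fixes that coordinate and re-minimizes
#' over the rest; for a function target the constrained minimum is obtained
#' by a quadratic-penalty ramp. If the profile never reaches the cutoff
#' within the search range the corresponding bound is reported as
#' `-Inf`/`Inf` and flagged (a flat profile signals a non-identifiable
#' target).
#'
#' @param objective Function: parameter vector -> -2 log likelihood.
#' @param par Parameter vector at the minimum (as from [fit_model()]).
#' @param target Integer index into `par`, or function `par -> scalar`.
#' @param level Confidence level in `[0, 1)`; `level = 0` collapses the
#'   interval to the point estimate.
#' @param max_expand Maximum number of bracket doublings per side.
#' @return Numeric `c(low, high)` with attributes `value` (the point
#'   estimate of the target) and `flags` (character, e.g.
#'   `"unbounded_low"`).
#' @export
profile_interval <- function(objective, par, target, level = 0.95,
                             max_expand = 40L) {
  g <- if (is.function(target)) target else function(p) p[[target]]
  v_hat <- g(par)
  f0 <- objective(par)
  if (level < 0 || level >= 1) stopf("`level` must be in [0, 1)")
  crit <- stats::qchisq(level, df = 1)
  if (crit == 0) {
    return(structure(c(v_hat, v_hat), value = v_hat, flags = character()))
  }
  idx_target <- !is.function(target)
  scale_f <- max(1, abs(f0))

  prof <- local({
    warm <- par
    function(v) {
      if (idx_target) {
        free <- setdiff(seq_along(par), target)
        if (!length(free)) return(objective(replace(par, target, v)))
        fn_red <- function(th) {
          full <- warm
          full[free] <- th
          full[[target]] <- v
          objective(full)
        }
        o <- stats::optim(warm[free], fn_red, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-10,
                                         ndeps = rep(1e-6, length(free))))
        warm[free] <<- o$par
        o$value
      } else {
        th <- warm
        val <- NA_real_
        for (w in c(1e2, 1e4, 1e6) * scale_f) {
          fn_pen <- function(t_) objective(t_) + w * (g(t_) - v)^2
          o <- stats::optim(th, fn_pen, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10,
                                           ndeps = rep(1e-6, length(th))))
          th <- o$par
          val <- objective(th)
        }
        warm <<- th
        val
      }
    }
  })

  flags <- character()
  one_side <- function(dir) {
    step <- max(abs(v_hat), 0.1) * 0.1
    v_lo <- v_hat
    q_lo <- -crit
    for (i in seq_len(max_expand)) {
      v_hi <- v_hat + dir * step * 2^(i - 1)
      q_hi <- prof(v_hi) - f0 - crit
      if (is.finite(q_hi) && q_hi >= 0) {
        r <- stats::uniroot(function(v) prof(v) - f0 - crit,
                            lower = min(v_lo, v_hi), upper = max(v_lo, v_hi),
                            f.lower = if (dir > 0) q_lo else q_hi,
                            f.upper = if (dir > 0) q_hi else q_lo,
                            tol = max(abs(v_hat), 0.1) * 1e-5)
        return(r$root)
      }
      v_lo <- v_hi
      q_lo <- q_hi
    }
    flags <<- c(flags, if (dir < 0) "unbounded_low" else "unbounded_high")
    dir * Inf
  }
  low <- one_side(-1)
  high <- one_side(1)
  structure(c(low, high), value = v_hat, flags = flags)
}

#' Profile-likelihood confidence interval for a twin-model target
#'
#' Profiles the FIML -2 log likelihood of a fitted twin model over a scalar
#' function of its parameters -- typically a standardized variance share
#' such as the additive-genetic proportion at a given wave. Bounds are the
#' target values at which the profiled -2LL rises by the chi-square(1)
#' quantile above the minimum. If profiling fails numerically, a percentile
#' bootstrap over pairs (resampled within zygosity) is used and flagged in
#' the result.
#'
#' @param fit A converged [fit_model()] result.
#' @param data The data the model was fitted to ([twin_pairs] or
#'   [twin_moments]).
#' @param target For ACE fits, a function of a [cholesky_params] object
#'   returning a scalar (e.g.
#'   `function(p) standardize(p)$totals["12y", "A"]`); for other kinds, a
#'   function of the raw parameter vector or a parameter index.
#' @param level Confidence level.
#' @param clip Optional length-2 numeric; bounds are clipped to this range
#'   (use `c(0, 1)` for standardized shares, which live in the unit
#'   interval by construction).
#' @param boot_B Bootstrap replicates for the fallback.
#' @return List with `low`, `high`, `value`, `level`, `method`
#'   (`"profile"` or `"bootstrap"`) and `flags`.
#' @export
profile_ci <- function(fit, data, target, level = 0.95, clip = NULL,
                       boot_B = 200L) {
  stopifnot(inherits(fit, "twin_fit"))
  if (!fit$converged) stopf("profile_ci() needs a converged fit")
  mom <- as_twin_moments(data)
  ob <- model_objective(fit$model, mom)
  tfun <- if (fit$model == "ace" && is.function(target)) {
    function(theta) target(theta_to_params(theta))
  } else target
  res <- tryCatch(
    profile_interval(ob$fn, fit$theta, tfun, level = level),
    error = function(e) e)
  if (inherits(res, "error") || any(!is.finite(res))) {
    if (inherits(data, "twin_moments")) {
      if (inherits(res, "error")) stop(res)
      out <- list(low = res[1L], high = res[2L], value = attr(res, "value"),
                  level = level, method = "profile", flags = attr(res, "flags"))
      return(out)
    }
    stat <- if (fit$model == "ace" && is.function(target)) {
      function(f) target(f$params)
    } else if (is.function(target)) {
      function(f) target(f$theta)
    } else function(f) f$theta[[target]]
    bci <- bootstrap_ci(data, fit$model, stat, B = boot_B, level = level,
                        seed = fit$seed)
    out <- list(low = bci$low, high = bci$high, value = bci$value,
                level = level, method = "bootstrap", flags = "profile_failed")
  } else {
    out <- list(low = res[1L], high = res[2L], value = attr(res, "value"),
                level = level, method = "profile", flags = attr(res, "flags"))
  }
  if (!is.null(clip)) {
    out$low <- max(out$low, clip[1L])
    out$high <- min(out$high, clip[2L])
  }
  out
}

# Resample pairs with replacement within zygosity, preserving structure.
#' @noRd
resample_pairs <- function(x) {
  d <- x$data
  idx <- unlist(lapply(split(seq_len(nrow(d)), d$zygosity), function(i) {
    sample(i, length(i), replace = TRUE)
  }), use.names = FALSE)
  d <- d[idx, , drop = FALSE]
  d$pair_id <- as.character(seq_len(nrow(d)))
  rownames(d) <- NULL
  out <- x
  out$data <- d
  out
}

#' Percentile bootstrap confidence interval for a twin-model statistic
#'
#' Resamples pairs with replacement within each zygosity group, refits the
#' model on each replicate, and returns percentile bounds of the statistic.
#'
#' @param data A [twin_pairs] dataset.
#' @param model Model kind, as for [fit_model()].
#' @param statistic Function of a `twin_fit` returning a scalar.
#' @param B Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed (replicates are deterministic given it).
#' @param starts Optimization starts per replicate fit.
#' @return List with `low`, `high`, `value` (statistic at the full-data
#'   fit), `level`, `B_effective` (replicates whose fit converged).
#' @export
bootstrap_ci <- function(data, model, statistic, B = 200L, level = 0.95,
                         seed = 1L, starts = 1L) {
  stopifnot(inherits(data, "twin_pairs"))
  full <- fit_model(data, model, starts = starts, seed = seed)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      rep_fit <- tryCatch(
        fit_model(resample_pairs(data), model, starts = starts, seed = seed),
        error = function(e) NULL)
      if (is.null(rep_fit) || !rep_fit$converged) NA_real_ else statistic(rep_fit)
    }, numeric(1))
  })
  vals <- vals[is.finite(vals)]
  if (length(vals) < 10L) stopf("too few successful bootstrap replicates (%d)", length(vals))
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(low = q[1L], high = q[2L], value = statistic(full), level = level,
       B_effective = length(vals))
}
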
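#' Run the full longitudinal twin analysis sequence
#'
#' Executes the standard analysis pipeline on a twin-pair dataset:
#' residualization of scores on sex and age, the twin correlation report,
#' the model-fitting ladder (fully saturated baseline, order-constrained
#' and order+zygosity-constrained sub-models, full ACE Cholesky) with
#' likelihood-ratio comparisons (sub-model 1a vs saturated, 1b vs 1a, ACE
#' vs saturated), and the standardized variance decomposition of the ACE
#' solution. Optionally writes the report bundle to disk as CSV tables
#' plus machine-readable JSON with a run log (seed, package version,
#' convergence diagnostics).
#'
#' @param data A [twin_pairs] object, a path to a pairs CSV, or `NULL` to
#'   simulate from `sim_config`.
#' @param sim_config A [simulation_config()] used when `data` is `NULL`
#'   (defaults to [gemini_like_config()]).
#' @param models Character vector of models to fit (subset of
#'   `"saturated"`, `"sub1a"`, `"sub1b"`, `"ace"`); validated before any
#'   computation.
#' @param residualize Residualize scores first (skipped when the data
#'   already are).
#' @param ci `"none"` (default), `"profile"` or `"bootstrap"`: confidence
#'   intervals for the standardized A/C/E totals of the ACE fit.
#' @param ci_level Confidence level for intervals.
#' @param seed Integer seed used for simulation, fitting restarts and
#'   bootstrap.
#' @param starts Optimization starts for the ACE fit.
#' @param out_dir Optional output directory; created if needed. On any
#'   stage failure, files already written there by this run are removed.
#' @return A list (class `twin_analysis`) with elements `dataset`,
#'   `correlations`, `fits`, `fit_table` (Table-1-style data frame),
#'   `comparisons`, `decomposition` (and `decomposition_table`), `cis`
#'   (when requested) and `log`.
#' @export
run_full_analysis <- function(data = NULL, sim_config = NULL,
                              models = c("saturated", "sub1a", "sub1b", "ace"),
                              residualize = TRUE,
                              ci = c("none", "profile", "bootstrap"),
                              ci_level = 0.95, seed = 1L, starts = 5L,
                              out_dir = NULL) {
  ci <- match.arg(ci)
  known <- c("saturated", "sub1a", "sub1b", "ace")
  bad <- setdiff(models, known)
  if (length(bad)) stopf("unknown model name(s): %s", paste(bad, collapse = ", "))
  if (!length(models)) stopf("no models requested")

  written <- character()
  log <- list(seed = seed, package_version = as.character(utils::packageVersion("twinace")),
              r_version = R.version.string, stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      unlink(written)
      stopf("stage \"%s\" failed: %s", name, conditionMessage(e))
    })
    log$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  dataset <- stage("data", {
    if (is.null(data)) {
      cfg <- sim_config %||% gemini_like_config()
      simulate_cohort(cfg, seed = seed)
    } else if (is.character(data)) {
      read_pairs_csv(data)
    } else if (inherits(data, "twin_pairs")) data
    else stopf("`data` must be a twin_pairs object, a CSV path, or NULL")
  })

  if (residualize && !dataset$residualized) {
    dataset <- stage("residualize", residualize_scores(dataset))
  }

  correlations <- stage("correlations", correlation_report(dataset, level = ci_level))

  fits <- list()
  for (m in models) {
    fits[[m]] <- stage(paste0("fit_", m),
                       fit_model(dataset, m, starts = if (m == "ace") starts else NULL,
                                 seed = seed))
    log$stages[[paste0("fit_", m)]]$converged <- fits[[m]]$converged
  }

  comparisons <- stage("comparisons", {
    plan <- list(c("sub1a", "saturated"), c("sub1b", "sub1a"), c("ace", "saturated"))
    out <- list()
    for (p in plan) {
      if (all(p %in% names(fits))) {
        out[[paste(p, collapse = "_vs_")]] <- compare_models(fits[[p[2L]]], fits[[p[1L]]])
      }
    }
    out
  })

  fit_table <- do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    cmp_name <- grep(paste0("^", m, "_vs_"), names(comparisons), value = TRUE)
    cmp <- if (length(cmp_name)) comparisons[[cmp_name[1L]]] else NULL
    data.frame(model = m, compared_to = if (is.null(cmp)) NA_character_ else cmp$full,
               ep = f$ep, df = f$df, minus2ll = f$minus2ll, aic = f$aic,
               delta_chi2 = if (is.null(cmp)) NA_real_ else cmp$delta_chi2,
               delta_df = if (is.null(cmp)) NA_integer_ else cmp$delta_df,
               p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
               converged = f$converged, stringsAsFactors = FALSE)
  }))

  decomposition <- if ("ace" %in% names(fits)) {
    stage("decomposition", standardize(fits$ace))
  } else NULL

  cis <- NULL
  if (ci != "none" && "ace" %in% names(fits)) {
    cis <- stage("intervals", {
      targets <- expand.grid(wave = wave_labels(), component = c("A", "C", "E"),
                             stringsAsFactors = FALSE)
      out <- list()
      for (i in seq_len(nrow(targets))) {
        wv <- targets$wave[i]; comp <- targets$component[i]
        tf <- local({
          wv0 <- wv; comp0 <- comp
          function(p) standardize(p)$totals[wv0, comp0]
        })
        key <- paste0(comp, "_", wv)
        out[[key]] <- if (ci == "profile") {
          profile_ci(fits$ace, dataset, tf, level = ci_level, clip = c(0, 1))
        } else {
          bootstrap_ci(dataset, "ace", function(f) tf(f$params),
                       level = ci_level, seed = seed)
        }
      }
      out
    })
  }

  log$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  bundle <- structure(list(dataset = dataset, correlations = correlations,
                           fits = fits, fit_table = fit_table,
                           comparisons = comparisons,
                           decomposition = decomposition,
                           decomposition_table = if (is.null(decomposition)) NULL
                                                 else as.data.frame(decomposition),
                           cis = cis, log = log),
                      class = "twin_analysis")

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(obj, name, writer) {
        path <- file.path(out_dir, name)
        writer(obj, path)
        written <<- c(written, path)
      }
      wr(fit_table, "fit_statistics.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
      wr(as.data.frame(correlations), "correlations.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
      if (!is.null(bundle$decomposition_table)) {
        wr(bundle$decomposition_table, "decomposition.csv",
           function(o, p) utils::write.csv(o, p, row.names = FALSE))
      }
      json <- list(fit_table = fit_table,
                   decomposition = bundle$decomposition_table,
                   cis = cis,
                   estimates = lapply(fits, function(f) as.list(f$estimates)))
      wr(json, "results.json",
         function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE))
      wr(log, "run_log.json",
         function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, pretty = TRUE))
      invisible(NULL)
    })
  }
  bundle
}

#' @export
print.twin_analysis <- function(x, ...) {
  cat("<twin_analysis>\n")
  print(x$dataset)
  cat("\nFit statistics:\n")
  print(x$fit_table, row.names = FALSE, digits = 6)
  if (!is.null(x$decomposition)) {
    cat("\nStandardized totals:\n")
    print(round(x$decomposition$totals, 3))
  }
  invisible(x)
}
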
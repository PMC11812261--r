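#' Fisher z confidence interval for a correlation
#'
#' Standard Fisher transform interval
#' `tanh(atanh(r) +/- z / sqrt(n - 3))`, with `z` the two-sided normal
#' quantile at `level`.
#'
#' @param r Correlation estimate, `|r| <= 1`.
#' @param n Effective sample size (number of independent pairs; must be at
#'   least 4).
#' @param level Confidence level in `(0, 1]`.
#' @return Numeric vector `c(ci_low, ci_high)`. When `|r| = 1` the interval
#'   degenerates to `(r, r)` with a warning.
#' @export
fisher_interval <- function(r, n, level = 0.95) {
  if (!is.finite(r) || abs(r) > 1) stopf("`r` must be a correlation in [-1, 1]")
  if (n < 4) stopf("`n` must be at least 4 for a Fisher interval")
  if (level <= 0 || level > 1) stopf("`level` must be in (0, 1]")
  if (abs(r) == 1) {
    warnf("|r| = 1: Fisher interval is degenerate")
    return(c(r, r))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z / sqrt(n - 3)
  tanh(atanh(r) + c(-half, half))
}

#' Double-entry Pearson correlation for twin pairs
#'
#' Computes the Pearson correlation on the double-entered sample
#' `{(x, y)} U {(y, x)}`, which makes the estimate invariant to the
#' (arbitrary) ordering of twins within a pair. This is the conventional
#' way to compute intraclass-style twin correlations from pair data.
#'
#' @param x,y Numeric vectors: the two members' values, one element per
#'   pair. Pairs where either member is missing are dropped.
#' @param level Confidence level for the Fisher interval.
#' @return An object of class `correlation_estimate`: a list with elements
#'   `r`, `ci_low`, `ci_high` and `n_pairs` (complete pairs used; doubled
#'   entries are counted once).
#' @export
double_entry_correlation <- function(x, y, level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs, got %d", n)
  xx <- c(x, y); yy <- c(y, x)
  if (stats::sd(xx) == 0 || stats::sd(yy) == 0) {
    stopf("correlation undefined: zero variance in double-entered sample")
  }
  r <- stats::cor(xx, yy)
  r <- max(-1, min(1, r))
  ci <- if (n >= 4) fisher_interval(r, n, level) else c(NA_real_, NA_real_)
  structure(list(r = r, ci_low = ci[1L], ci_high = ci[2L], n_pairs = n),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("r = %.3f (%.3f, %.3f), n = %d pairs\n",
              x$r, x$ci_low, x$ci_high, x$n_pairs))
  invisible(x)
}

# Double-entered cell sample for arbitrary slot pairs: each pair contributes
# the entry (slot_i, slot_j) and its twin-order mirror.
#' @noRd
cell_sample <- function(Y, i, j) {
  swap <- function(k) if (k > 3L) k - 3L else k + 3L
  x <- c(Y[, i], Y[, swap(i)])
  y <- c(Y[, j], Y[, swap(j)])
  keep <- !is.na(x) & !is.na(y)
  # pairs contributing at least one complete entry, counted once
  n <- nrow(Y)
  contrib <- keep[seq_len(n)] | keep[n + seq_len(n)]
  list(x = x[keep], y = y[keep], n_pairs = sum(contrib))
}

#' Twin correlation report (Table-3-style)
#'
#' For each zygosity group, fills the 6 x 6 grid over (twin x wave) slots
#' with double-entry Pearson correlations: cross-twin within-time
#' (intraclass), cross-twin cross-time, and within-twin cross-time cells.
#' Confidence intervals use the Fisher transform with the number of
#' contributing pairs as effective n. Cells are computed from all pairs
#' complete for that cell (pairwise deletion), mirroring FIML's use of
#' partial records. Within-twin cross-time correlations are additionally
#' reported pooled over zygosity.
#'
#' @param x A residualized [twin_pairs] object.
#' @param level Confidence level.
#' @return An object of class `correlation_report`: per zygosity, matrices
#'   `r`, `ci_low`, `ci_high`, `n_pairs` with `t1/t2 x wave` slots, plus a
#'   `pooled_within_twin` data frame.
#' @export
correlation_report <- function(x, level = 0.95) {
  stopifnot(inherits(x, "twin_pairs"))
  if (!x$residualized) {
    stopf("correlation_report() expects residualized scores; run residualize_scores() first")
  }
  groups <- list(MZ = score_matrix(x)[x$data$zygosity == "MZ", , drop = FALSE],
                 DZ = score_matrix(x)[x$data$zygosity == "DZ", , drop = FALSE])
  one_group <- function(Y) {
    p <- 6L
    r <- lo <- hi <- matrix(NA_real_, p, p, dimnames = list(slot_labels(), slot_labels()))
    np <- matrix(NA_integer_, p, p, dimnames = dimnames(r))
    diag(r) <- 1
    for (i in seq_len(p - 1L)) {
      for (j in seq.int(i + 1L, p)) {
        s <- cell_sample(Y, i, j)
        est <- tryCatch({
          if (length(s$x) < 3L) stopf("fewer than 3 complete entries")
          if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0) stopf("zero variance")
          rr <- max(-1, min(1, stats::cor(s$x, s$y)))
          ci <- if (s$n_pairs >= 4 && abs(rr) < 1) {
            fisher_interval(rr, s$n_pairs, level)
          } else c(NA_real_, NA_real_)
          list(r = rr, ci = ci, n = s$n_pairs)
        },
          error = function(e) {
            warnf("correlation cell (%s, %s) unavailable: %s",
                  slot_labels()[i], slot_labels()[j], conditionMessage(e))
            NULL
          })
        if (!is.null(est)) {
          r[i, j] <- r[j, i] <- est$r
          lo[i, j] <- lo[j, i] <- est$ci[1L]
          hi[i, j] <- hi[j, i] <- est$ci[2L]
          np[i, j] <- np[j, i] <- est$n
        }
      }
    }
    list(r = r, ci_low = lo, ci_high = hi, n_pairs = np)
  }
  rep_ <- lapply(groups, one_group)

  # pooled within-twin cross-time correlations (both zygosities together)
  Yall <- score_matrix(x)
  pooled <- do.call(rbind, lapply(list(c(1L, 2L), c(1L, 3L), c(2L, 3L)), function(ij) {
    s <- cell_sample(Yall, ij[1L], ij[2L])
    rr <- if (length(s$x) >= 3L) stats::cor(s$x, s$y) else NA_real_
    ci <- if (!is.na(rr) && s$n_pairs >= 4 && abs(rr) < 1) {
      fisher_interval(rr, s$n_pairs, level)
    } else c(NA_real_, NA_real_)
    data.frame(wave_i = wave_labels()[ij[1L]], wave_j = wave_labels()[ij[2L]],
               r = rr, ci_low = ci[1L], ci_high = ci[2L], n_pairs = s$n_pairs)
  }))
  structure(list(MZ = rep_$MZ, DZ = rep_$DZ, pooled_within_twin = pooled,
                 level = level),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  fmt_block <- function(g, zyg) {
    cat(sprintf("%s twins (n cells are contributing pairs):\n", zyg))
    m <- matrix("", 6, 6, dimnames = dimnames(g$r))
    for (i in 1:6) for (j in 1:6) {
      if (i == j) m[i, j] <- "1"
      else if (j < i && !is.na(g$r[i, j])) {
        m[i, j] <- sprintf("%.*f (%.*f, %.*f)", digits, g$r[i, j],
                           digits, g$ci_low[i, j], digits, g$ci_high[i, j])
      }
    }
    print(m, quote = FALSE)
    cat("\n")
  }
  fmt_block(x$MZ, "Monozygotic")
  fmt_block(x$DZ, "Dizygotic")
  cat("Pooled within-twin cross-time correlations:\n")
  print(x$pooled_within_twin, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Flatten a correlation report to a long data frame
#'
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @return Data frame with one row per unique cell and zygosity:
#'   `zygosity`, `row_slot`, `col_slot`, `r`, `ci_low`, `ci_high`,
#'   `n_pairs`.
#' @export
as.data.frame.correlation_report <- function(x, ...) {
  out <- list()
  for (zyg in c("MZ", "DZ")) {
    g <- x[[zyg]]
    for (i in 1:5) for (j in seq.int(i + 1L, 6L)) {
      out[[length(out) + 1L]] <- data.frame(
        zygosity = zyg, row_slot = slot_labels()[i], col_slot = slot_labels()[j],
        r = g$r[i, j], ci_low = g$ci_low[i, j], ci_high = g$ci_high[i, j],
        n_pairs = g$n_pairs[i, j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
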
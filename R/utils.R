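# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
wave_labels <- function() c("16m", "5y", "12y")

# Slot order used throughout for the 6-variate twin vector.
#' @noRd
slot_labels <- function() {
  as.vector(outer(wave_labels(), c("t1", "t2"), function(w, t) paste(t, w, sep = "_")))
}

# Column names of the per-pair score block, in slot order.
#' @noRd
score_columns <- function() {
  as.vector(outer(wave_labels(), c("t1", "t2"),
                  function(w, t) paste0("eoe_", t, "_", w)))
}

#' @noRd
age_columns <- function() paste0("age_", wave_labels())

# Fill a p x p lower-triangular matrix column-major from a vector
# (p = 3: order 11, 21, 31, 22, 32, 33).
#' @noRd
vec_to_lower <- function(v, p = 3L) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- v
  m
}

#' @noRd
lower_to_vec <- function(m) m[lower.tri(m, diag = TRUE)]

#' @noRd
lower_names <- function(prefix, p = 3L) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  paste0(prefix, idx[, "row"], idx[, "col"])
}

# Symmetrize (guards tiny asymmetries before chol()).
#' @noRd
symm <- function(m) (m + t(m)) / 2

# Nearest PSD-ish repair: floor eigenvalues. Used only for starting values.
#' @noRd
psd_floor <- function(m, floor = 1e-3) {
  e <- eigen(symm(m), symmetric = TRUE)
  d <- pmax(e$values, floor)
  symm(e$vectors %*% (d * t(e$vectors)))
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)
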
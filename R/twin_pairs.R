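#' Twin-pair longitudinal dataset
#'
#' Wraps a wide table of twin pairs (one row per pair) holding zygosity,
#' per-twin sex, per-wave age and per-twin per-wave EOE scores for up to
#' three measurement waves (16 months, 5 years, 12 years). Pairs with no
#' observed EOE score at any wave are excluded at construction, matching the
#' inclusion rule of cohort analyses (at least one time point observed).
#'
#' @param data A data frame with columns `pair_id`, `zygosity` (`"MZ"` or
#'   `"DZ"`), `sex_t1`, `sex_t2` (`"M"` or `"F"`), `age_16m`, `age_5y`,
#'   `age_12y` (age at each wave; months at 16 months, years later), and the
#'   six score columns `eoe_t1_16m`, `eoe_t2_16m`, `eoe_t1_5y`, `eoe_t2_5y`,
#'   `eoe_t1_12y`, `eoe_t2_12y`. Missing values are `NA`.
#' @param residualized Logical; `TRUE` marks scores that are already
#'   residuals of the sex/age regression (see [residualize_scores()]).
#'   Residualized (and otherwise centred/latent-scale) scores are exempt
#'   from the raw `[1, 5]` range check.
#' @param range_check Warn when raw scores fall outside `[1, 5]`. Disabled
#'   automatically for residualized data and for latent-scale simulated
#'   scores.
#' @return An object of class `twin_pairs`.
#' @seealso [read_pairs_csv()], [residualize_scores()], [simulate_cohort()]
#' @export
twin_pairs <- function(data, residualized = FALSE, range_check = !residualized) {
  need <- c("pair_id", "zygosity", "sex_t1", "sex_t2", age_columns(), score_columns())
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("twin-pair table lacks column(s): %s", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[need]
  data$pair_id <- as.character(data$pair_id)

  dup <- data$pair_id[duplicated(data$pair_id)]
  if (length(dup)) stopf("duplicate pair_id: %s", paste(unique(dup), collapse = ", "))

  bad_zyg <- !data$zygosity %in% c("MZ", "DZ")
  if (any(bad_zyg)) {
    stopf("unknown zygosity token for pair(s) %s (must be \"MZ\" or \"DZ\")",
          paste(utils::head(data$pair_id[bad_zyg], 5L), collapse = ", "))
  }
  bad_sex <- !(data$sex_t1 %in% c("M", "F")) | !(data$sex_t2 %in% c("M", "F"))
  if (any(bad_sex)) {
    stopf("invalid sex code for pair(s) %s (must be \"M\" or \"F\")",
          paste(utils::head(data$pair_id[bad_sex], 5L), collapse = ", "))
  }
  os_mz <- data$zygosity == "MZ" & data$sex_t1 != data$sex_t2
  if (any(os_mz)) {
    stopf("opposite-sex pair(s) labelled MZ: %s",
          paste(utils::head(data$pair_id[os_mz], 5L), collapse = ", "))
  }

  sc <- as.matrix(data[score_columns()])
  storage.mode(sc) <- "double"
  if (range_check) {
    out_of_range <- sc[!is.na(sc)]
    out_of_range <- out_of_range[out_of_range < 1 | out_of_range > 5]
    if (length(out_of_range)) {
      warnf("%d EOE score(s) outside [1, 5]; raw CEBQ subscale means lie in that range",
            length(out_of_range))
    }
  }
  none <- rowSums(!is.na(sc)) == 0L
  if (any(none)) {
    message(sprintf("excluding %d pair(s) with no observed EOE score at any wave",
                    sum(none)))
    data <- data[!none, , drop = FALSE]
  }
  rownames(data) <- NULL
  structure(list(data = data, waves = wave_labels(), residualized = residualized),
            class = "twin_pairs")
}

#' @export
print.twin_pairs <- function(x, ...) {
  d <- x$data
  sc <- score_matrix(x)
  cat(sprintf("<twin_pairs> %d pairs (%d MZ, %d DZ)%s\n",
              nrow(d), sum(d$zygosity == "MZ"), sum(d$zygosity == "DZ"),
              if (x$residualized) ", residualized scores" else ""))
  obs <- colSums(!is.na(sc))
  per_wave <- obs[1:3] + obs[4:6]
  cat(sprintf("  individuals with scores: %s\n",
              paste(sprintf("%s: %d", x$waves, per_wave), collapse = ", ")))
  invisible(x)
}

# n x 6 score matrix in slot order (t1_16m, t1_5y, t1_12y, t2_16m, ...).
#' @noRd
score_matrix <- function(x) {
  m <- as.matrix(x$data[score_columns()])
  storage.mode(m) <- "double"
  colnames(m) <- slot_labels()
  m
}

#' Read and write twin-pair CSV files
#'
#' The CSV contract is one row per pair with columns `pair_id`, `zygosity`
#' (`MZ`/`DZ`), `sex_t1`, `sex_t2` (`M`/`F`), `age_16m`, `age_5y`,
#' `age_12y`, `eoe_t1_16m`, `eoe_t2_16m`, `eoe_t1_5y`, `eoe_t2_5y`,
#' `eoe_t1_12y`, `eoe_t2_12y`. Missing values are empty fields. Numeric
#' values are written with 17 significant digits so that a write/read
#' round trip reproduces them exactly.
#'
#' @param path File path.
#' @param residualized Passed to [twin_pairs()]; set `TRUE` when the file
#'   holds residualized scores.
#' @return `read_pairs_csv()` returns a [twin_pairs] object;
#'   `write_pairs_csv()` invisibly returns `path`.
#' @export
read_pairs_csv <- function(path, residualized = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(pair_id = "character",
                                        zygosity = "character",
                                        sex_t1 = "character",
                                        sex_t2 = "character"),
                         na.strings = "")
  num <- c(age_columns(), score_columns())
  for (nm in intersect(num, names(raw))) raw[[nm]] <- as.numeric(raw[[nm]])
  twin_pairs(raw, residualized = residualized)
}

#' @param x A [twin_pairs] object.
#' @rdname read_pairs_csv
#' @export
write_pairs_csv <- function(x, path) {
  stopifnot(inherits(x, "twin_pairs"))
  d <- x$data
  for (nm in c(age_columns(), score_columns())) {
    v <- d[[nm]]
    d[[nm]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Attach item-level scores to a pair table
#'
#' Merges EOE scores computed from a long item-level table (see
#' [score_items_long()]) into the wide score columns of a twin-pair data
#' frame, leaving other columns untouched.
#'
#' @param pairs A data frame following the twin-pair column contract (or a
#'   [twin_pairs] object, whose underlying table is used).
#' @param items Long-format item table, as for [score_items_long()].
#' @return A [twin_pairs] object with scores replaced by the item-derived
#'   subscale means.
#' @export
attach_item_scores <- function(pairs, items) {
  d <- if (inherits(pairs, "twin_pairs")) pairs$data else as.data.frame(pairs)
  sc <- score_items_long(items)
  for (i in seq_len(nrow(sc))) {
    col <- sprintf("eoe_t%d_%s", sc$twin[i], sc$wave[i])
    row <- match(as.character(sc$pair_id[i]), as.character(d$pair_id))
    if (is.na(row)) stopf("item table refers to unknown pair_id %s", sc$pair_id[i])
    d[row, col] <- sc$eoe[i]
  }
  twin_pairs(d)
}
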
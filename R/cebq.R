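#' Score the CEBQ emotional-overeating subscale
#'
#' Computes the emotional-overeating (EOE) subscale score as the mean of the
#' completed item responses. The standard CEBQ subscale has four items (used
#' at 5 and 12 years); the toddler adaptation (CEBQ-T, used at 16 months)
#' has three. A score is returned only when at least two items were
#' completed; otherwise the score is missing, mirroring the completion rule
#' used for these instruments (minimum 2/3 items on the toddler scale,
#' 2/4 on the standard scale).
#'
#' @param items Integer (or integer-valued numeric) vector of Likert
#'   responses in `1:5`; `NA` marks an item left blank. Length must equal
#'   `scale_length`.
#' @param scale_length Number of items on the scale: 3 (CEBQ-T) or 4 (CEBQ).
#' @return The mean of the present responses (a value in `[1, 5]`), or `NA`
#'   if fewer than two items were completed.
#' @examples
#' score_cebq_eoe(c(2, 3, 4, 3), 4)      # 3.0
#' score_cebq_eoe(c(2, 3, NA, NA), 4)    # 2.5 -- two items suffice
#' score_cebq_eoe(c(2, NA, NA), 3)       # NA  -- completion rule fails
#' @export
score_cebq_eoe <- function(items, scale_length = length(items)) {
  if (!scale_length %in% c(3L, 4L)) {
    stopf("`scale_length` must be 3 (CEBQ-T) or 4 (CEBQ), got %s", scale_length)
  }
  if (length(items) != scale_length) {
    stopf("expected %d item slots, got %d", scale_length, length(items))
  }
  bad <- which(!is.na(items) & (items < 1 | items > 5 | items != round(items)))
  if (length(bad)) {
    stopf("item %d is not a Likert response in 1..5 (value: %s)",
          bad[1L], format(items[bad[1L]]))
  }
  present <- !is.na(items)
  if (sum(present) < 2L) return(NA_real_)
  mean(as.numeric(items[present]))
}

#' Score a long-format item-level table
#'
#' Takes item-level CEBQ responses in long format (one row per pair, twin,
#' wave and item) and returns one EOE score per twin and wave, applying the
#' subscale completion rule via [score_cebq_eoe()]. Waves labelled `"16m"`
#' are scored on the 3-item toddler scale; `"5y"` and `"12y"` on the 4-item
#' scale.
#'
#' @param items A data frame with columns `pair_id`, `twin` (1 or 2),
#'   `wave` (one of `"16m"`, `"5y"`, `"12y"`), `item_index`, `response`.
#' @return A data frame with columns `pair_id`, `twin`, `wave`, `eoe`.
#' @export
score_items_long <- function(items) {
  need <- c("pair_id", "twin", "wave", "item_index", "response")
  miss <- setdiff(need, names(items))
  if (length(miss)) stopf("item table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!all(items$wave %in% wave_labels())) {
    stopf("unknown wave label(s): %s",
          paste(unique(setdiff(items$wave, wave_labels())), collapse = ", "))
  }
  key <- interaction(items$pair_id, items$twin, items$wave, drop = TRUE)
  out <- lapply(split(items, key), function(d) {
    k <- if (d$wave[1L] == "16m") 3L else 4L
    resp <- rep(NA_real_, k)
    resp[d$item_index] <- d$response
    data.frame(pair_id = d$pair_id[1L], twin = d$twin[1L], wave = d$wave[1L],
               eoe = score_cebq_eoe(resp, k), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$pair_id, out$twin, match(out$wave, wave_labels())), , drop = FALSE]
}
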
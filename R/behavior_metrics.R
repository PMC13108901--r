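# Group-level behavioral signatures: per-pair accuracy, learned vs
# non-learned accuracy, serial-position curves, symbolic-distance slopes.

#' Per-pair accuracy from testing-phase choices
#'
#' For every unordered rank pair, the fraction of trials on which the truly
#' higher-ranked item was chosen. Pairs never tested are kept with `NA`
#' accuracy rather than 0.
#'
#' @param choices a choice table (testing-phase rows used).
#' @param rank the true [rank_order()].
#' @return data.frame of class `pair_accuracy` with columns `lo`, `hi`
#'   (rank positions, lo < hi), `n`, `n_correct`, `accuracy`, covering all
#'   `choose(n, 2)` pairs; attribute `n_items`.
#' @export
pair_accuracy <- function(choices, rank = rank_order()) {
  counts <- choice_counts(choices, rank)
  allp <- t(utils::combn(rank$n, 2))
  out <- data.frame(lo = allp[, 1], hi = allp[, 2])
  m <- match(paste(out$lo, out$hi), paste(counts$lo, counts$hi))
  out$n <- ifelse(is.na(m), 0L, counts$n[m])
  out$n_correct <- ifelse(is.na(m), NA_integer_, counts$n_hi[m])
  out$accuracy <- ifelse(out$n > 0, out$n_correct / out$n, NA_real_)
  structure(out, n_items = rank$n, class = c("pair_accuracy", "data.frame"))
}

# build a pair_accuracy object directly from a vector of 28 accuracies in
# canonical (lo, hi) order — used by permutation machinery
pair_accuracy_from_values <- function(values, n_items = 8L, n_trials = 10L) {
  allp <- t(utils::combn(n_items, 2))
  structure(data.frame(lo = allp[, 1], hi = allp[, 2],
                       n = n_trials, n_correct = round(values * n_trials),
                       accuracy = values),
            n_items = n_items, class = c("pair_accuracy", "data.frame"))
}

#' Serial-position curve
#'
#' Mean accuracy per rank position, averaged over the `n - 1` pairs that
#' contain the position. End positions of a ranking typically exceed middle
#' positions (U shape) for value-based choosers.
#'
#' @param pa a [pair_accuracy()].
#' @return named numeric vector of length `n_items` (position -> accuracy).
#' @export
serial_position_curve <- function(pa) {
  n_items <- attr(pa, "n_items")
  vapply(seq_len(n_items), function(r) {
    mean(pa$accuracy[pa$lo == r | pa$hi == r], na.rm = TRUE)
  }, numeric(1))
}

#' Symbolic-distance effect slope
#'
#' Ordinary-least-squares slope of pair accuracy on rank distance
#' (`hi - lo`, 1..n-1). A positive slope is the classic symbolic-distance
#' effect: larger rank separations are judged more accurately.
#'
#' @param pa a [pair_accuracy()].
#' @return the OLS slope (accuracy units per rank-distance unit).
#' @export
distance_effect_slope <- function(pa) {
  d <- pa$hi - pa$lo
  keep <- !is.na(pa$accuracy)
  if (length(unique(d[keep])) < 2L) stop_input("all rank distances equal; slope undefined")
  unname(stats::coef(stats::lm(pa$accuracy[keep] ~ d[keep]))[2])
}

#' Mean accuracy for learned vs non-learned pairs
#'
#' @param pa a [pair_accuracy()].
#' @param pairs the learned [pair_set()].
#' @return named numeric vector `c(learned = ..., nonlearned = ...)`.
#' @export
learned_vs_nonlearned <- function(pa, pairs = pair_set()) {
  key <- paste(pairs[, 1], pairs[, 2])
  is_learned <- paste(pa$lo, pa$hi) %in% key
  c(learned = mean(pa$accuracy[is_learned], na.rm = TRUE),
    nonlearned = mean(pa$accuracy[!is_learned], na.rm = TRUE))
}

#' Overall testing accuracy of a subject
#'
#' @param pa a [pair_accuracy()].
#' @return trial-weighted mean accuracy.
#' @export
overall_accuracy <- function(pa) {
  keep <- pa$n > 0
  sum(pa$n_correct[keep]) / sum(pa$n[keep])
}

#' Below-chance cohort filter
#'
#' Drops subjects whose overall testing accuracy is below 0.5; applied
#' before all cohort-level analyses.
#'
#' @param pas named list of [pair_accuracy()] objects (one per subject).
#' @return the list restricted to subjects at or above chance; dropped
#'   subject ids are attached as attribute `"excluded"`.
#' @export
filter_below_chance <- function(pas) {
  acc <- vapply(pas, overall_accuracy, numeric(1))
  keep <- acc >= 0.5
  structure(pas[keep], excluded = names(pas)[!keep])
}
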
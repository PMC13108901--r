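# Error-structure analyses: Beta-distribution bimodality classification,
# consistent-error thresholds, circular-triad self-consistency with a
# permutation test, and participant categorization.

#' Majority-direction tournament from pair accuracies
#'
#' Each unordered pair is directed toward the item chosen on the majority
#' of trials: accuracy > 0.5 directs the pair toward the truly higher rank,
#' accuracy < 0.5 toward the lower. A pair at exactly 0.5 is resolved
#' toward the error direction (majority correctness requires strictly more
#' than half correct) and counted in the `ties` attribute.
#'
#' @param pa a [pair_accuracy()] with no missing entries.
#' @return object of class `tournament`: list with `n_items` and logical
#'   matrix `wins` (`wins[a, b]` is `TRUE` iff position a is judged above
#'   position b).
#' @export
majority_tournament <- function(pa) {
  n_items <- attr(pa, "n_items")
  if (anyNA(pa$accuracy)) stop_input("tournament requires an accuracy for every pair")
  wins <- matrix(FALSE, n_items, n_items)
  ties <- 0L
  for (k in seq_len(nrow(pa))) {
    lo <- pa$lo[k]; hi <- pa$hi[k]; acc <- pa$accuracy[k]
    if (acc == 0.5) ties <- ties + 1L
    if (acc > 0.5) wins[hi, lo] <- TRUE else wins[lo, hi] <- TRUE
  }
  structure(list(n_items = n_items, wins = wins, ties = ties),
            class = "tournament")
}

# tournament directly from a rank permutation (higher subjective rank wins)
tournament_from_order <- function(perm) {
  n <- length(perm)
  wins <- outer(perm, perm, ">")
  diag(wins) <- FALSE
  structure(list(n_items = n, wins = wins, ties = 0L), class = "tournament")
}

check_tournament <- function(t) {
  n <- t$n_items
  w <- t$wins
  ok <- all((w | t(w))[upper.tri(w)]) && !any((w & t(w))[upper.tri(w)]) && !any(diag(w))
  if (!ok) stop_input("tournament is not complete and antisymmetric")
}

#' Count circular (intransitive) triads in a tournament
#'
#' A triad is circular when its three directed judgments form a cycle
#' (each of the three items beats exactly one other within the triad).
#' `method = "enumeration"` checks every 3-item subset directly;
#' `method = "scores"` uses the score-sequence identity
#' `C(n,3) - sum_i C(w_i, 2)` with `w_i` the number of wins of item i.
#' The two routes agree on every complete tournament.
#'
#' @param t a `tournament`.
#' @param method counting route.
#' @return integer number of circular triads.
#' @export
count_circular_triads <- function(t, method = c("enumeration", "scores")) {
  method <- match.arg(method)
  check_tournament(t)
  n <- t$n_items
  if (method == "scores") {
    w <- rowSums(t$wins)
    return(as.integer(choose(n, 3) - sum(choose(w, 2))))
  }
  triads <- utils::combn(n, 3)
  n_circ <- 0L
  for (k in seq_len(ncol(triads))) {
    idx <- triads[, k]
    sub <- t$wins[idx, idx]
    if (all(rowSums(sub) == 1L)) n_circ <- n_circ + 1L
  }
  n_circ
}

#' Maximum possible number of circular triads
#'
#' For n items: `(n^3 - n)/24` when n is odd, `(n^3 - 4n)/24` when n is
#' even. For 8 items the maximum is 20.
#'
#' @param n number of items (>= 3).
#' @return integer maximum.
#' @export
max_circular_triads <- function(n) {
  if (any(n < 3)) stop_input("n must be >= 3")
  as.integer(ifelse(n %% 2 == 1, (n^3 - n) / 24, (n^3 - 4 * n) / 24))
}

#' Ranking self-consistency coefficient and category
#'
#' The coefficient is `1 - Nd / NT`, where `Nd` is the observed number of
#' circular triads and `NT` the maximum attainable for the item count
#' (20 for 8 items). It equals 1 exactly when the tournament admits a
#' strict total order. Categories: `correct` if every pair is directed as
#' the true order; `consistent_incorrect` if transitive but different from
#' the true order; `inconsistent` if any circular triad exists.
#'
#' @param t a `tournament` over true rank positions.
#' @param nt denominator; defaults to [max_circular_triads()] of the item
#'   count (an all-triads denominator such as 56 for 8 items may be
#'   supplied instead).
#' @return list with `coefficient`, `n_circular`, `category`.
#' @export
self_consistency <- function(t, nt = max_circular_triads(t$n_items)) {
  nd <- count_circular_triads(t, method = "scores")
  truth <- outer(seq_len(t$n_items), seq_len(t$n_items), ">")
  category <- if (nd > 0) {
    "inconsistent"
  } else if (identical(t$wins, truth)) {
    "correct"
  } else {
    "consistent_incorrect"
  }
  list(coefficient = 1 - nd / nt, n_circular = nd, category = category)
}

#' Permutation test for group-level ranking self-consistency
#'
#' The observed statistic is the mean self-consistency coefficient across
#' subjects. Each permutation shuffles every subject's pair-accuracy values
#' across the pair positions (preserving the per-subject multiset of
#' accuracies), rebuilds the majority tournaments, and recomputes the group
#' statistic. The p-value uses the add-one convention
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param pas list of [pair_accuracy()] objects (one per subject).
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer seed.
#' @param nt denominator for the coefficients (see [self_consistency()]).
#' @return list with `observed`, `null` (numeric vector), `p`.
#' @export
permutation_test_consistency <- function(pas, n_perm = 1000L, seed = 1L,
                                         nt = NULL) {
  n_items <- attr(pas[[1]], "n_items")
  allp <- t(utils::combn(n_items, 2))
  lo <- allp[, 1]; hi <- allp[, 2]
  denom <- if (is.null(nt)) max_circular_triads(n_items) else nt
  n_triads <- choose(n_items, 3)
  # score-sequence identity, directly on an accuracy vector in canonical
  # (lo, hi) order: exact ties go to the error direction (lower item wins)
  coef_of <- function(values) {
    winners <- ifelse(values > 0.5, hi, lo)
    w <- tabulate(winners, n_items)
    1 - (n_triads - sum(choose(w, 2))) / denom
  }
  vals <- lapply(pas, function(pa) pa$accuracy)
  observed <- mean(vapply(vals, coef_of, numeric(1)))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      mean(vapply(vals, function(v) coef_of(sample(v)), numeric(1)))
    }, numeric(1))
  })
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}

#' Consistent-error pairs of one subject
#'
#' Pairs whose error proportion (1 - accuracy) reaches the threshold. With
#' 10 trials per pair the natural thresholds are 0.6, 0.7, 0.8, 0.9, 1.0.
#'
#' @param pa a [pair_accuracy()].
#' @param threshold error-proportion threshold.
#' @return data.frame of the qualifying pairs (subset of `pa`).
#' @export
consistent_error_pairs <- function(pa, threshold = 0.8) {
  if (!threshold %in% c(0.6, 0.7, 0.8, 0.9, 1.0)) {
    warning("threshold outside the design's natural grid (0.6..1.0)")
  }
  err <- 1 - pa$accuracy
  pa[!is.na(err) & err >= threshold, , drop = FALSE]
}

#' Cohort counts of subjects with at least one consistent-error pair
#'
#' @param pas list of [pair_accuracy()] objects.
#' @param thresholds error-proportion thresholds.
#' @return data.frame with `threshold`, `count`, `proportion`; counts are
#'   non-increasing in the threshold.
#' @export
cohort_consistency_counts <- function(pas, thresholds = seq(0.6, 1.0, by = 0.1)) {
  if (length(pas) == 0L) stop_input("empty cohort")
  counts <- vapply(thresholds, function(th) {
    sum(vapply(pas, function(pa) nrow(consistent_error_pairs(pa, th)) > 0,
               logical(1)))
  }, numeric(1))
  data.frame(threshold = thresholds, count = as.integer(counts),
             proportion = counts / length(pas))
}

#' Error-consistency score of one subject
#'
#' Mean error proportion over the subject's majority-error pairs (pairs
#' with accuracy at or below 0.5; exact ties count as errors, matching the
#' majority rule that defines a pair as correct only above 50%). Undefined
#' (NA) for subjects with no majority-error pair, who belong to the
#' correct-ranking group.
#'
#' @param pa a [pair_accuracy()].
#' @return mean error proportion in \[0.5, 1\], or NA.
#' @export
error_consistency_score <- function(pa) {
  err <- 1 - pa$accuracy
  sel <- !is.na(err) & err >= 0.5
  if (!any(sel)) return(NA_real_)
  mean(err[sel])
}

#' Fit a Beta distribution to accuracies and classify its shape
#'
#' Maximum-likelihood fit of Beta(alpha, beta) to a vector of accuracies,
#' with a method-of-moments fallback on non-convergence. Boundary values
#' (exact 0 or 1 break the likelihood) are first shrunk by
#' `x' = (x * (N - 1) + 0.5) / N`. Shape classification: both parameters
#' above 1 is unimodal (interior mode); `alpha > 1 >= beta` high-accuracy;
#' `beta > 1 >= alpha` low-accuracy; both at or below 1 bimodal (mass
#' concentrated at the extremes).
#'
#' @param accuracies numeric vector in \[0, 1\], length >= 5.
#' @param shrink apply the boundary shrink (default TRUE).
#' @return list with `alpha_hat`, `beta_hat`, `category`, `method`
#'   (`"mle"` or `"moments"`), `degenerate` flag.
#' @export
fit_beta <- function(accuracies, shrink = TRUE) {
  x <- accuracies
  if (length(x) < 5L) stop_input("need at least 5 values to fit a Beta")
  if (any(x < 0 | x > 1)) stop_input("accuracies must lie in [0, 1]")
  n <- length(x)
  if (shrink) x <- (x * (n - 1) + 0.5) / n
  degenerate <- stats::var(x) < 1e-12
  if (degenerate) {
    # no spread: classify from the mean alone
    category <- if (mean(x) > 0.5) "high_accuracy" else "low_accuracy"
    return(list(alpha_hat = NA_real_, beta_hat = NA_real_,
                category = category, method = "degenerate",
                degenerate = TRUE))
  }
  fit <- tryCatch(
    suppressWarnings(fitdistrplus::fitdist(x, "beta")),
    error = function(e) NULL
  )
  if (!is.null(fit) && all(is.finite(fit$estimate)) && all(fit$estimate > 0)) {
    a <- unname(fit$estimate["shape1"]); b <- unname(fit$estimate["shape2"])
    method <- "mle"
  } else {
    m <- mean(x); v <- stats::var(x)
    k <- m * (1 - m) / v - 1
    a <- m * k; b <- (1 - m) * k
    method <- "moments"
  }
  category <- if (a > 1 && b > 1) "unimodal"
  else if (a > 1) "high_accuracy"
  else if (b > 1) "low_accuracy"
  else "bimodal"
  list(alpha_hat = a, beta_hat = b, category = category, method = method,
       degenerate = FALSE)
}

#' Classify Beta shape parameters
#'
#' The classification rule of [fit_beta()] applied to given shapes.
#'
#' @param alpha_hat,beta_hat positive shape parameters.
#' @return one of `"unimodal"`, `"high_accuracy"`, `"low_accuracy"`,
#'   `"bimodal"`.
#' @export
beta_category <- function(alpha_hat, beta_hat) {
  if (alpha_hat > 1 && beta_hat > 1) "unimodal"
  else if (alpha_hat > 1) "high_accuracy"
  else if (beta_hat > 1) "low_accuracy"
  else "bimodal"
}
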
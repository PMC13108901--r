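# HodgeRank reconstruction of each subject's global subjective ranking
# from pairwise judgments, and inter-subject ranking similarity.

#' Pairwise preference matrix from testing-phase choices
#'
#' For each ordered item pair (i, j), the mean of +/-1 trial codes (+1 when
#' i was chosen over j). Antisymmetric with zero diagonal; pairs never
#' tested are NA (the HodgeRank solver accepts incomplete comparison
#' graphs).
#'
#' @param choices a choice table (testing-phase rows used).
#' @param items item labels fixing row/column order (default: labels seen
#'   in the table, sorted).
#' @return antisymmetric numeric matrix with dimnames `items`.
#' @export
preference_matrix <- function(choices, items = NULL) {
  tp <- choices[choices$phase == "testing", , drop = FALSE]
  if (nrow(tp) == 0L) stop_input("no testing-phase choices")
  if (is.null(items)) items <- sort(unique(c(tp$item_i, tp$item_j)))
  n <- length(items)
  s <- matrix(0, n, n, dimnames = list(items, items))   # sum of codes
  cnt <- matrix(0L, n, n)
  for (t in seq_len(nrow(tp))) {
    i <- match(tp$item_i[t], items); j <- match(tp$item_j[t], items)
    code <- if (tp$chosen_item[t] == tp$item_i[t]) 1 else -1
    s[i, j] <- s[i, j] + code; s[j, i] <- s[j, i] - code
    cnt[i, j] <- cnt[i, j] + 1L; cnt[j, i] <- cnt[j, i] + 1L
  }
  y <- ifelse(cnt > 0, s / pmax(cnt, 1L), NA_real_)
  diag(y) <- 0
  dimnames(y) <- list(items, items)
  y
}

#' HodgeRank: least-squares global scores from pairwise preferences
#'
#' Finds the score vector s minimizing `sum over observed pairs of
#' (s_i - s_j - Y_ij)^2`. On a complete comparison graph the solution is
#' the row mean `s_i = mean_j Y_ij`; in general it solves the graph
#' Laplacian normal equations via pseudoinverse, which requires a connected
#' comparison graph. Scores are centered to sum zero (they are defined only
#' up to an additive constant); the subjective order sorts items by score,
#' with exact ties broken by item label order (flagged).
#'
#' @param y an antisymmetric preference matrix from [preference_matrix()]
#'   (NA = unobserved pair).
#' @return list of class `subjective_ranking` with `scores` (named,
#'   centered), `order` (a [rank_order()]; rank 1 = lowest score), and
#'   `ties` (number of tied score pairs broken by label).
#' @export
hodgerank <- function(y) {
  n <- nrow(y)
  items <- rownames(y)
  if (is.null(items)) items <- as.character(seq_len(n))
  obs <- !is.na(y) & upper.tri(y)
  edges <- which(obs, arr.ind = TRUE)
  if (nrow(edges) == 0L) stop_input("no observed pairs")
  # connectivity of the comparison graph
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (k in seq_len(nrow(edges))) {
      m <- min(comp[edges[k, 1]], comp[edges[k, 2]])
      new[edges[k, 1]] <- min(new[edges[k, 1]], m)
      new[edges[k, 2]] <- min(new[edges[k, 2]], m)
    }
    if (identical(new, comp)) break
    comp <- new
  }
  if (length(unique(comp)) > 1L) {
    stop_input("comparison graph is disconnected (components: %s)",
               paste(tapply(items, comp, paste, collapse = ","), collapse = " | "))
  }
  adj <- !is.na(y); diag(adj) <- FALSE
  L <- diag(rowSums(adj)) - adj * 1
  b <- rowSums(ifelse(is.na(y), 0, y))
  s <- as.numeric(MASS::ginv(L) %*% b)
  s <- s - mean(s)
  names(s) <- items
  ties <- sum(duplicated(round(s, 12)))
  ord <- order(s, items)
  structure(list(scores = s, order = rank_order(items[ord]), ties = ties),
            class = "subjective_ranking")
}

#' Kendall's tau between two rank orders
#'
#' @param a,b [rank_order()] objects over the same item set.
#' @return tau in \[-1, 1\].
#' @export
kendall_tau <- function(a, b) {
  if (!setequal(names(a$rank), names(b$rank))) stop_input("item sets differ")
  items <- names(a$rank)
  unname(stats::cor(a$rank[items], b$rank[items], method = "kendall"))
}

#' All pairwise inter-subject ranking similarities
#'
#' Kendall's tau between the global rank orders of every pair of subjects.
#'
#' @param rankings list of [rank_order()] objects (or `subjective_ranking`
#'   objects, whose `$order` is used), length >= 2.
#' @return data.frame with `a`, `b` (indices or names), `tau`; the mean tau
#'   is attached as attribute `"mean_tau"`.
#' @export
inter_subject_similarity <- function(rankings) {
  if (length(rankings) < 2L) stop_input("need at least 2 rankings")
  rankings <- lapply(rankings, function(r) if (inherits(r, "subjective_ranking")) r$order else r)
  ids <- names(rankings)
  if (is.null(ids)) ids <- as.character(seq_along(rankings))
  idx <- t(utils::combn(length(rankings), 2))
  tau <- vapply(seq_len(nrow(idx)), function(k) {
    kendall_tau(rankings[[idx[k, 1]]], rankings[[idx[k, 2]]])
  }, numeric(1))
  structure(data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]], tau = tau),
            mean_tau = mean(tau))
}
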
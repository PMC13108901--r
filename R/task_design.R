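# Experimental structure: items and their ranks, the fixed learned-pair set,
# and the trial schedules for the learning, testing, and sequential (MEG)
# phases.

#' Create a rank order over items
#'
#' A rank order is a bijection between item labels and ranks `1..n`
#' (1 = lowest). Without a seed the items keep their given order; with a
#' seed the assignment of labels to ranks is a reproducible random
#' permutation, mirroring a design in which each participant learns a
#' freshly shuffled ranking over the same item set.
#'
#' @param items character vector of distinct item labels (default `LETTERS[1:8]`).
#' @param seed optional integer; if supplied, labels are randomly permuted.
#' @return An object of class `rank_order` with components `items` (labels
#'   sorted by rank, position r = item of rank r) and `rank` (named integer
#'   vector mapping label to rank).
#' @examples
#' ro <- rank_order()
#' ro$rank["H"]  # 8
#' @export
rank_order <- function(items = LETTERS[1:8], seed = NULL) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop_input("duplicate item labels")
  if (length(items) < 2L) stop_input("need at least 2 items")
  ord <- if (is.null(seed)) items else with_seed(seed, sample(items))
  rank <- stats::setNames(seq_along(ord), ord)
  structure(list(items = ord, rank = rank, n = length(items)),
            class = "rank_order")
}

#' @export
print.rank_order <- function(x, ...) {
  cat("Rank order (1 = lowest):", paste(x$items, collapse = " < "), "\n")
  invisible(x)
}

# item label at a given rank
item_at_rank <- function(ro, r) ro$items[r]

# rank of a given item label
rank_of <- function(ro, item) unname(ro$rank[item])

#' The fixed set of learned pairs
#'
#' The default learning set contains eight pairs given as rank positions:
#' (1,6), (2,3), (2,5), (3,7), (4,6), (4,7), (5,8), (1,8) — i.e. with items
#' A..H at ranks 1..8: (A,F), (B,C), (B,E), (C,G), (D,F), (D,G), (E,H),
#' (A,H). Every rank position occurs in exactly two pairs and the rank
#' distances span 1..7.
#'
#' @param pairs two-column integer matrix of rank-position pairs; defaults
#'   to the fixed eight-pair learning set.
#' @return A `pair_set`: a two-column matrix (lo, hi) of rank positions.
#' @export
pair_set <- function(pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- rbind(c(1, 6), c(2, 3), c(2, 5), c(3, 7),
                   c(4, 6), c(4, 7), c(5, 8), c(1, 8))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || nrow(pairs) < 1L) stop_input("pair set must be a k x 2 matrix")
  if (any(pairs[, 1] == pairs[, 2])) stop_input("pairs must contain distinct ranks")
  m <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  colnames(m) <- c("lo", "hi")
  structure(m, class = c("pair_set", "matrix"))
}

#' Signed normalized rank distance
#'
#' `D(m, n) = (m - n) / (n_items - 1)`: the signed difference of two rank
#' positions scaled so that the maximal distance between the extremes of an
#' n-item ranking is 1. Antisymmetric in its arguments. This is the teaching
#' signal shown to the learning models.
#'
#' @param m,n rank positions in `1..n_items` (vectorized).
#' @param n_items number of items (default 8).
#' @return `(m - n) / (n_items - 1)`.
#' @examples
#' signed_rank_distance(6, 1)   # 5/7
#' @export
signed_rank_distance <- function(m, n, n_items = 8L) {
  if (n_items < 2L) stop_input("n_items must be >= 2")
  if (any(m < 1 | m > n_items | n < 1 | n > n_items)) {
    stop_input("ranks must lie in 1..n_items")
  }
  (m - n) / (n_items - 1)
}

new_schedule <- function(phase, block, trial, rank_a, rank_b) {
  data.frame(phase = phase, block = block, trial = trial,
             rank_a = rank_a, rank_b = rank_b,
             stringsAsFactors = FALSE)
}

#' Build a learning-phase schedule
#'
#' Each pair of the pair set is presented exactly once per block, in an
#' independently randomized order within each block.
#'
#' @param pairs a [pair_set()].
#' @param n_blocks number of learning blocks (default 4).
#' @param seed integer seed for the within-block shuffles.
#' @return data.frame with columns phase, block, trial, rank_a, rank_b.
#' @export
build_learning_schedule <- function(pairs = pair_set(), n_blocks = 4L, seed = 1L) {
  if (nrow(pairs) == 0L) stop_input("empty pair set")
  if (n_blocks < 1L) stop_input("n_blocks must be >= 1")
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      ord <- sample(nrow(pairs))
      cbind(b, pairs[ord, , drop = FALSE])
    }))
    new_schedule("learning", rows[, 1], seq_len(nrow(rows)), rows[, 2], rows[, 3])
  })
}

#' Build a testing-phase schedule
#'
#' All `choose(n_items, 2)` pairs are tested exactly once per block in a
#' random sequence (no feedback is assumed by the simulators).
#'
#' @param n_items number of items (default 8).
#' @param n_blocks number of testing blocks (default 10).
#' @param seed integer seed.
#' @return data.frame with columns phase, block, trial, rank_a, rank_b.
#' @export
build_test_schedule <- function(n_items = 8L, n_blocks = 10L, seed = 1L) {
  if (n_items < 2L) stop_input("n_items must be >= 2")
  if (n_blocks < 1L) stop_input("n_blocks must be >= 1")
  allp <- t(utils::combn(n_items, 2))
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      ord <- sample(nrow(allp))
      cbind(b, allp[ord, , drop = FALSE])
    }))
    new_schedule("testing", rows[, 1], seq_len(nrow(rows)), rows[, 2], rows[, 3])
  })
}

#' Build a sequential single-item stream (MEG-style testing)
#'
#' Each block presents a stream of single items built by concatenating
#' independently shuffled sequences of all items and slicing the stream into
#' blocks of `images_per_block` images. Consecutive images define the judged
#' pairs, so a block of k images yields k - 1 pairwise judgments (the first
#' image of a block yields none).
#'
#' @param n_items number of items (default 8).
#' @param n_blocks number of blocks (default 5).
#' @param images_per_block images per block (default 81, giving 80 judgments).
#' @param seed integer seed.
#' @return data.frame with columns phase, block, trial, rank_a, rank_b;
#'   `rank_a` is the presented item's rank and `rank_b` is `NA` (single-item
#'   stream).
#' @export
build_meg_sequence <- function(n_items = 8L, n_blocks = 5L,
                               images_per_block = 81L, seed = 1L) {
  if (images_per_block < 2L) stop_input("images_per_block must be >= 2")
  total <- n_blocks * images_per_block
  with_seed(seed, {
    stream <- integer(0)
    while (length(stream) < total) stream <- c(stream, sample(n_items))
    stream <- stream[seq_len(total)]
    new_schedule("meg", rep(seq_len(n_blocks), each = images_per_block),
                 seq_len(total), stream, NA_integer_)
  })
}
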
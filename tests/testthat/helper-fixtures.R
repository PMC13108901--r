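# Shared fixtures, all built in code.

# Deterministic choice table with a prescribed number of correct choices
# per unordered rank pair (canonical combn(n, 2) order).
fixture_choices <- function(n_correct, n_trials = 10L, n_items = 8L,
                            truth = rank_order(LETTERS[seq_len(n_items)]),
                            subject_id = "s1") {
  allp <- t(combn(n_items, 2))
  stopifnot(length(n_correct) == nrow(allp), all(n_correct <= n_trials))
  rows <- do.call(rbind, lapply(seq_len(nrow(allp)), function(k) {
    lo <- allp[k, 1]; hi <- allp[k, 2]
    correct <- c(rep(TRUE, n_correct[k]), rep(FALSE, n_trials - n_correct[k]))
    data.frame(
      subject_id = subject_id, phase = "testing",
      block = seq_len(n_trials), trial = k + (seq_len(n_trials) - 1) * nrow(allp),
      item_i = truth$items[lo], item_j = truth$items[hi],
      chosen_item = ifelse(correct, truth$items[hi], truth$items[lo]),
      is_correct = as.integer(correct), stringsAsFactors = FALSE
    )
  }))
  rows
}

# pair_accuracy object from a plain accuracy vector in canonical order
fixture_pa <- function(values, n_items = 8L, n_trials = 10L) {
  tinfer:::pair_accuracy_from_values(values, n_items, n_trials)
}

# uniformly random complete tournament
random_tournament <- function(n, seed) {
  set.seed(seed)
  wins <- matrix(FALSE, n, n)
  for (k in seq_len(choose(n, 2))) NULL
  pairs <- t(combn(n, 2))
  up <- runif(nrow(pairs)) < 0.5
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    if (up[k]) wins[b, a] <- TRUE else wins[a, b] <- TRUE
  }
  structure(list(n_items = n, wins = wins, ties = 0L), class = "tournament")
}

# tournament implied by a rank permutation (higher rank wins every pair)
order_tournament <- function(perm) tinfer:::tournament_from_order(perm)

# brute-force circular-triad count by checking every 3-subset
brute_triads <- function(t) {
  n <- t$n_items
  triads <- combn(n, 3)
  sum(vapply(seq_len(ncol(triads)), function(k) {
    idx <- triads[, k]
    all(rowSums(t$wins[idx, idx]) == 1L)
  }, logical(1)))
}

# noiseless +/-1 preference matrix implied by a rank permutation over items
noiseless_preferences <- function(perm, items = LETTERS[seq_along(perm)]) {
  y <- sign(outer(perm, perm, "-"))
  diag(y) <- 0
  dimnames(y) <- list(items, items)
  y
}
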
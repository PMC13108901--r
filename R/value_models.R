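# The five computational agents for transitive inference. All learning
# operates in rank space: a pair is a pair of true rank positions (m, n),
# and the teaching signal is the signed normalized distance D(m, n)
# (see signed_rank_distance). Item labels only enter when choices are
# rendered into a choice table.

MODELS <- c("qlearning", "betaq", "betasort", "distance_avg", "correct_rank")

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop_input("alpha must lie in (0, 1]")
  }
}

#' Q-learning delta-rule update for one presented pair
#'
#' When a pair of rank positions (m, n) is presented, both values move
#' toward the presented signed distance:
#' `Qm <- Qm + alpha * (D(m,n) - (Qm - Qn)) / 2` and symmetrically for Qn.
#' Both right-hand sides read pre-update values, so the update conserves
#' `sum(Q)` exactly.
#'
#' @param q numeric value vector indexed by rank position (init all 0).
#' @param m,n presented rank positions (distinct).
#' @param alpha learning rate in (0, 1].
#' @return updated value vector.
#' @export
qlearning_update <- function(q, m, n, alpha) {
  check_alpha(alpha)
  if (m == n) stop_input("pair must contain distinct ranks")
  n_items <- length(q)
  D <- signed_rank_distance(m, n, n_items)
  qm <- q[m]; qn <- q[n]
  q[m] <- qm + alpha * (D - (qm - qn)) / 2
  q[n] <- qn + alpha * (-D - (qn - qm)) / 2
  q
}

#' Logistic (softmax) choice probability for a pair
#'
#' `p(i over j) = 1 / (1 + exp(-gamma * (qi - qj)))` with inverse
#' temperature `gamma >= 0`; `gamma = 0` yields chance for any values.
#'
#' @param qi,qj item values.
#' @param gamma inverse temperature (>= 0).
#' @return probability of choosing the item with value `qi`.
#' @export
softmax_choice_prob <- function(qi, qj, gamma) {
  if (any(gamma < 0)) stop_input("gamma must be >= 0")
  stats::plogis(gamma * (qi - qj))
}

#' Initial Beta state
#'
#' Every item starts at Beta(1, 1), the uniform distribution on \[0, 1\].
#'
#' @param n_items number of items.
#' @return list with positive shape vectors `u` and `l`.
#' @export
beta_state <- function(n_items = 8L) {
  list(u = rep(1, n_items), l = rep(1, n_items))
}

beta_means <- function(state) state$u / (state$u + state$l)

check_beta_state <- function(state) {
  if (any(state$u <= 0) || any(state$l <= 0)) {
    stop_input("Beta shape parameters must be positive")
  }
}

# Shapes may be driven non-positive by the printed updates over long runs;
# clamped at eps so the Beta density stays defined.
clamp_beta <- function(state, eps = 1e-6) {
  state$u <- pmax(state$u, eps)
  state$l <- pmax(state$l, eps)
  state
}

#' Beta-Q update for one presented pair
#'
#' The presented pair's Beta shape parameters move by the mismatch between
#' the presented signed distance and the current expected-value difference
#' `dV = Vm - Vn` (V = U / (U + L)), with the bias factor `alpha` weighting
#' the two downward-pulling terms:
#' `Um += D - dV`, `Lm += alpha * (-D + dV)`, `Un += alpha * (-D + dV)`,
#' `Ln += D - dV`. All right-hand sides read pre-update values; the pair is
#' oriented so that `m` is the truly higher rank. Shapes are clamped at a
#' small positive floor afterwards.
#'
#' @param state a [beta_state()].
#' @param m,n presented rank positions; internally oriented so m > n.
#' @param alpha bias factor in (0, 1].
#' @param eps positive clamp floor for the shape parameters.
#' @return updated state.
#' @export
betaq_update <- function(state, m, n, alpha, eps = 1e-6) {
  check_alpha(alpha)
  check_beta_state(state)
  if (m == n) stop_input("pair must contain distinct ranks")
  if (m < n) { tmp <- m; m <- n; n <- tmp }
  n_items <- length(state$u)
  D <- signed_rank_distance(m, n, n_items)
  V <- beta_means(state)
  dV <- V[m] - V[n]
  state$u[m] <- state$u[m] + (D - dV)
  state$l[m] <- state$l[m] + alpha * (-D + dV)
  state$u[n] <- state$u[n] + alpha * (-D + dV)
  state$l[n] <- state$l[n] + (D - dV)
  clamp_beta(state, eps)
}

#' Betasort update: presented pair plus all non-presented items
#'
#' Extends [betaq_update()] by also updating every non-presented item `o`,
#' with the case chosen from pre-update expected values (m oriented above n,
#' `dV = Vm - Vn`):
#' \itemize{
#'   \item `Vn <= Vo <= Vm` (ties included): the observation confirms the
#'     item's position, so concentration grows at fixed mean —
#'     `Uo += Vo`, `Lo += 1 - Vo`.
#'   \item `Vo < Vn`: `Uo += dV`, `Lo += alpha * dV`.
#'   \item `Vo > Vm`: `Uo += alpha * dV`, `Lo += dV`.
#' }
#' All case assignments and increments use pre-update values; the update is
#' applied atomically.
#'
#' @inheritParams betaq_update
#' @return updated state.
#' @export
betasort_update <- function(state, m, n, alpha, eps = 1e-6) {
  check_alpha(alpha)
  check_beta_state(state)
  if (m == n) stop_input("pair must contain distinct ranks")
  if (m < n) { tmp <- m; m <- n; n <- tmp }
  n_items <- length(state$u)
  V0 <- beta_means(state)
  dV <- V0[m] - V0[n]
  out <- betaq_update(state, m, n, alpha, eps)
  for (o in seq_len(n_items)) {
    if (o == m || o == n) next
    if (V0[o] >= V0[n] && V0[o] <= V0[m]) {
      out$u[o] <- state$u[o] + V0[o]
      out$l[o] <- state$l[o] + 1 - V0[o]
    } else if (V0[o] < V0[n]) {
      out$u[o] <- state$u[o] + dV
      out$l[o] <- state$l[o] + alpha * dV
    } else {
      out$u[o] <- state$u[o] + alpha * dV
      out$l[o] <- state$l[o] + dV
    }
  }
  clamp_beta(out, eps)
}

#' Probability that one Beta-distributed value exceeds another
#'
#' `P(Xi > Xj)` for independent `Xi ~ Beta(ui, li)`, `Xj ~ Beta(uj, lj)`.
#' The integral method evaluates the exact nested integral
#' `int dbeta(x; ui, li) * pbeta(x; uj, lj) dx` by adaptive quadrature;
#' the sampling method draws `n_samples` independent pairs and compares
#' them, matching a sampling-based choice policy.
#'
#' @param state a [beta_state()].
#' @param i,j rank positions to compare.
#' @param method "integral" (deterministic) or "sampling" (Monte Carlo).
#' @param n_samples samples for the sampling method.
#' @param seed seed for the sampling method.
#' @return probability of choosing item `i` over item `j`.
#' @export
beta_choice_prob <- function(state, i, j, method = c("integral", "sampling"),
                             n_samples = 10000L, seed = NULL) {
  method <- match.arg(method)
  check_beta_state(state)
  ui <- state$u[i]; li <- state$l[i]
  uj <- state$u[j]; lj <- state$l[j]
  if (method == "integral") {
    # P(Xi > Xj) = E_{Xi}[F_j(Xi)], integrated on the probability scale of
    # Xi (u -> F_j(Q_i(u))): the integrand is bounded in [0, 1] and stays
    # finite for arbitrarily extreme shape parameters, unlike the raw
    # density-times-CDF integrand
    # qbeta emits accuracy warnings for near-degenerate (clamped) shapes,
    # where the comparison is effectively deterministic anyway
    suppressWarnings(
      stats::integrate(function(u) stats::pbeta(stats::qbeta(u, ui, li), uj, lj),
                       0, 1, rel.tol = 1e-9)$value
    )
  } else {
    if (n_samples < 1L) stop_input("n_samples must be >= 1")
    with_seed(seed, mean(stats::rbeta(n_samples, ui, li) >
                           stats::rbeta(n_samples, uj, lj)))
  }
}

#' Distance-averaging values (non-learning baseline)
#'
#' Each item's value is the mean of its raw signed rank distances over all
#' learned pairs containing it: an item appearing in pairs at distances +3
#' and +7 gets value +5. No trial-by-trial updating occurs; distances are
#' in raw rank units, unlike the normalized distances the learning models
#' see.
#'
#' @param pairs a [pair_set()] of rank-position pairs.
#' @param n_items number of items (default: max rank in `pairs`).
#' @return numeric value vector indexed by rank position.
#' @export
distance_average_values <- function(pairs = pair_set(), n_items = max(pairs)) {
  q <- numeric(n_items)
  for (i in seq_len(n_items)) {
    rows <- which(pairs[, 1] == i | pairs[, 2] == i)
    if (length(rows) == 0L) stop_input("rank %d appears in no learned pair", i)
    partners <- ifelse(pairs[rows, 1] == i, pairs[rows, 2], pairs[rows, 1])
    q[i] <- mean(i - partners)
  }
  q
}

#' Correct-ranking values (oracle baseline)
#'
#' Each item's value is its true rank position: `Qi = ri`.
#'
#' @param n_items number of items.
#' @return numeric vector `1:n_items`.
#' @export
correct_ranking_values <- function(n_items = 8L) {
  as.numeric(seq_len(n_items))
}

# Deterministically reconstruct the end-of-learning state of a model from
# the learning schedule (learning involves no choices, so this has no
# latent variables). Returns a numeric value vector for softmax-policy
# models or a beta_state for the Beta models.
learn_end_state <- function(model, alpha, learn_sched, n_items = 8L) {
  model <- match.arg(model, MODELS)
  lp <- learn_sched[learn_sched$phase == "learning", , drop = FALSE]
  switch(model,
    qlearning = {
      q <- numeric(n_items)
      for (t in seq_len(nrow(lp))) {
        q <- qlearning_update(q, lp$rank_a[t], lp$rank_b[t], alpha)
      }
      q
    },
    betaq = {
      s <- beta_state(n_items)
      for (t in seq_len(nrow(lp))) {
        s <- betaq_update(s, lp$rank_a[t], lp$rank_b[t], alpha)
      }
      s
    },
    betasort = {
      s <- beta_state(n_items)
      for (t in seq_len(nrow(lp))) {
        s <- betasort_update(s, lp$rank_a[t], lp$rank_b[t], alpha)
      }
      s
    },
    distance_avg = distance_average_values(
      pair_set(unique(cbind(pmin(lp$rank_a, lp$rank_b),
                            pmax(lp$rank_a, lp$rank_b)))), n_items),
    correct_rank = correct_ranking_values(n_items)
  )
}

# Probability of choosing the truly higher-ranked item for each unordered
# pair (lo, hi), given a frozen end-of-learning state. Beta models use the
# exact comparison integral; the others a logistic policy with inverse
# temperature gamma.
pair_choice_probs <- function(model, state, gamma, pairs) {
  model <- match.arg(model, MODELS)
  if (model %in% c("betaq", "betasort")) {
    vapply(seq_len(nrow(pairs)), function(k) {
      beta_choice_prob(state, pairs[k, 2], pairs[k, 1], method = "integral")
    }, numeric(1))
  } else {
    softmax_choice_prob(state[pairs[, 2]], state[pairs[, 1]], gamma)
  }
}

#' Simulate one agent through learning and testing
#'
#' The agent's state is updated deterministically across the learning
#' schedule (no responses are made during learning), then frozen; testing
#' choices are drawn from the model's choice policy with no feedback and no
#' further updating. The Beta models choose by comparing independent draws
#' from each item's Beta value distribution (evaluated via the exact
#' integral); the other models use the logistic policy.
#'
#' @param model one of `"qlearning"`, `"betaq"`, `"betasort"`,
#'   `"distance_avg"`, `"correct_rank"`.
#' @param alpha learning rate / bias factor (ignored by the two baselines).
#' @param gamma inverse temperature (ignored by the Beta models' sampling
#'   policy).
#' @param rank a [rank_order()] giving item labels (truth: position r holds
#'   the item of rank r).
#' @param learn_sched,test_sched schedules from [build_learning_schedule()]
#'   and [build_test_schedule()].
#' @param seed integer seed for the choice draws.
#' @param subject_id subject identifier recorded in the table.
#' @param values optional numeric vector overriding the learned values
#'   (used e.g. for agents choosing from a subjective ranking); forces the
#'   logistic policy.
#' @return A choice table: data.frame with columns `subject_id`, `phase`,
#'   `block`, `trial`, `item_i`, `item_j`, `chosen_item`, `is_correct`.
#'   Presentation order of the two items is randomized per trial.
#' @export
simulate_agent <- function(model, alpha = 0.5, gamma = 1, rank = rank_order(),
                           learn_sched = build_learning_schedule(seed = 1L),
                           test_sched = build_test_schedule(seed = 1L),
                           seed = 1L, subject_id = "s1", values = NULL) {
  model <- match.arg(model, MODELS)
  if (gamma < 0) stop_input("gamma must be >= 0")
  n_items <- rank$n
  tp <- test_sched[test_sched$phase == "testing", , drop = FALSE]
  if (nrow(tp) == 0L) stop_input("test schedule has no testing rows")
  lo <- pmin(tp$rank_a, tp$rank_b); hi <- pmax(tp$rank_a, tp$rank_b)
  upairs <- unique(cbind(lo, hi))
  if (!is.null(values)) {
    p_hi <- softmax_choice_prob(values[upairs[, 2]], values[upairs[, 1]], gamma)
  } else {
    state <- learn_end_state(model, alpha, learn_sched, n_items)
    p_hi <- pair_choice_probs(model, state, gamma, upairs)
  }
  key <- paste(upairs[, 1], upairs[, 2])
  p <- p_hi[match(paste(lo, hi), key)]
  with_seed(seed, {
    chose_hi <- stats::runif(nrow(tp)) < p
    flip <- stats::runif(nrow(tp)) < 0.5  # randomized left/right presentation
    chosen_rank <- ifelse(chose_hi, hi, lo)
    data.frame(
      subject_id = subject_id,
      phase = "testing",
      block = tp$block,
      trial = tp$trial,
      item_i = item_at_rank(rank, ifelse(flip, hi, lo)),
      item_j = item_at_rank(rank, ifelse(flip, lo, hi)),
      chosen_item = item_at_rank(rank, chosen_rank),
      is_correct = as.integer(chose_hi),
      stringsAsFactors = FALSE
    )
  })
}
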
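# Maximum-likelihood estimation of per-subject model parameters from
# testing-phase choices. Because the learning phase involves no responses,
# the end-of-learning state is a deterministic function of (model, alpha,
# learning schedule) and the likelihood has no latent variables.

# Sufficient statistics of a choice table for all frozen-state policies:
# per unordered rank pair, how often the truly higher-ranked item was
# chosen and how often not.
choice_counts <- function(choices, rank) {
  tp <- choices[choices$phase == "testing", , drop = FALSE]
  if (nrow(tp) == 0L) stop_input("no testing-phase choices")
  ri <- rank_of(rank, tp$item_i)
  rj <- rank_of(rank, tp$item_j)
  rc <- rank_of(rank, tp$chosen_item)
  if (anyNA(c(ri, rj, rc))) stop_input("choice table contains unknown item labels")
  lo <- pmin(ri, rj); hi <- pmax(ri, rj)
  chose_hi <- rc == hi
  key <- paste(lo, hi)
  ag <- stats::aggregate(cbind(n_hi = chose_hi, n = rep(1L, length(key))),
                         by = list(lo = lo, hi = hi), FUN = sum)
  ag$n_lo <- ag$n - ag$n_hi
  ag
}

nll_from_counts <- function(model, alpha, gamma, counts, learn_sched, n_items,
                            p_floor = 1e-12) {
  state <- learn_end_state(model, alpha, learn_sched, n_items)
  p_hi <- pair_choice_probs(model, state, gamma,
                            cbind(counts$lo, counts$hi))
  p_hi <- pmin(pmax(p_hi, p_floor), 1 - p_floor)
  -sum(counts$n_hi * log(p_hi) + counts$n_lo * log(1 - p_hi))
}

#' Negative log-likelihood of testing-phase choices under a model
#'
#' The end-of-learning state is reconstructed deterministically from the
#' learning schedule, frozen, and the log probability of each observed test
#' choice is summed under the model's choice policy. Probabilities are
#' floored at `1e-12` to guard against underflow; at `gamma = 0` the value
#' is exactly `n_trials * log(2)`.
#'
#' @param model model id (see [simulate_agent()]).
#' @param alpha learning rate / bias factor.
#' @param gamma inverse temperature (unused by the Beta models).
#' @param choices a choice table (testing-phase rows are used).
#' @param learn_sched learning schedule used to reconstruct the state.
#' @param rank the true [rank_order()].
#' @return the negative log-likelihood (finite for finite parameters).
#' @export
negative_log_likelihood <- function(model, alpha, gamma, choices,
                                    learn_sched = build_learning_schedule(seed = 1L),
                                    rank = rank_order()) {
  counts <- choice_counts(choices, rank)
  nll_from_counts(model, alpha, gamma, counts, learn_sched, rank$n)
}

model_free_params <- function(model) {
  switch(model,
    qlearning = c("alpha", "gamma"),
    betaq = "alpha",
    betasort = "alpha",
    distance_avg = "gamma",
    correct_rank = "gamma"
  )
}

#' Fit a model to one subject's testing-phase choices
#'
#' Bounded maximum-likelihood estimation (`alpha` in (0, 1], `gamma` in
#' \[0, `gamma_max`\]) with multiple Latin-hypercube restarts of a
#' quasi-Newton optimizer; the best restart is returned. Deterministic
#' given `seed`. The Beta models have `alpha` as their only free parameter
#' (their sampling choice policy has no temperature); the two baseline
#' models only fit `gamma`.
#'
#' @inheritParams negative_log_likelihood
#' @param n_restarts number of optimizer restarts (default 10).
#' @param seed seed for the restart design.
#' @param gamma_max upper bound for the inverse temperature (default 100;
#'   the logistic saturates well below this for the value scales involved).
#' @return data.frame of class `fitted_params`: `model`, `alpha_hat`,
#'   `gamma_hat` (NA where the model has no such parameter), `nll`,
#'   `converged`, `n_trials`.
#' @export
fit_participant <- function(model, choices,
                            learn_sched = build_learning_schedule(seed = 1L),
                            rank = rank_order(), n_restarts = 10L, seed = 1L,
                            gamma_max = 100) {
  model <- match.arg(model, MODELS)
  counts <- choice_counts(choices, rank)
  n_trials <- sum(counts$n)
  free <- model_free_params(model)
  lower <- c(alpha = 1e-3, gamma = 0)[free]
  upper <- c(alpha = 1, gamma = gamma_max)[free]
  obj <- function(theta) {
    th <- stats::setNames(as.numeric(theta), free)
    nll_from_counts(model,
                    alpha = if ("alpha" %in% free) th[["alpha"]] else 0.5,
                    gamma = if ("gamma" %in% free) th[["gamma"]] else 1,
                    counts, learn_sched, rank$n)
  }
  starts <- with_seed(seed, lhs::randomLHS(n_restarts, length(free)))
  best <- NULL
  any_conv <- FALSE
  for (r in seq_len(n_restarts)) {
    th0 <- lower + starts[r, ] * (upper - lower)
    th0 <- pmin(pmax(th0, lower + 1e-6), upper - 1e-6)
    res <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(data.frame(model = model, alpha_hat = NA_real_,
                                gamma_hat = NA_real_, nll = NA_real_,
                                converged = FALSE, n_trials = n_trials),
                     class = c("fitted_params", "data.frame")))
  }
  th <- stats::setNames(as.numeric(best$par), free)
  structure(data.frame(
    model = model,
    alpha_hat = if ("alpha" %in% free) th[["alpha"]] else NA_real_,
    gamma_hat = if ("gamma" %in% free) th[["gamma"]] else NA_real_,
    nll = best$value,
    converged = any_conv,
    n_trials = n_trials
  ), class = c("fitted_params", "data.frame"))
}

#' Regenerate simulated choices from a fitted model
#'
#' Delegates to [simulate_agent()] with the best-fitting parameters and the
#' subject's learning schedule, so behavioral analyses can be run on
#' model-simulated responses exactly as on observed data.
#'
#' @param fit a `fitted_params` row from [fit_participant()].
#' @param learn_sched,test_sched schedules for the simulated run.
#' @param rank the true [rank_order()].
#' @param seed integer seed.
#' @param subject_id subject identifier for the simulated table.
#' @return a choice table (see [simulate_agent()]).
#' @export
simulate_from_fit <- function(fit, learn_sched, test_sched,
                              rank = rank_order(), seed = 1L,
                              subject_id = "sim") {
  simulate_agent(fit$model,
                 alpha = if (is.na(fit$alpha_hat)) 0.5 else fit$alpha_hat,
                 gamma = if (is.na(fit$gamma_hat)) 1 else fit$gamma_hat,
                 rank = rank, learn_sched = learn_sched,
                 test_sched = test_sched, seed = seed,
                 subject_id = subject_id)
}
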
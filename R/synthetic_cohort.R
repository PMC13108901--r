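# Seeded generation of complete synthetic datasets with the statistical
# structure the analyses assume: behavioral cohorts mixing value-model
# agents with "constructive" agents that hold idiosyncratic self-consistent
# subjective rankings, and MEG-like sensor patterns embedding known RDM
# structure in configurable time windows.

#' Cohort configuration
#'
#' Bundles every knob of the synthetic generators. All randomness flows
#' from `master_seed` through a documented sub-seed splitter, so any
#' cohort is exactly reproducible.
#'
#' @param n_subjects behavioral cohort size (default 77, the combined
#'   behavioral sample after exclusions).
#' @param mix named proportions over agent types (`qlearning`, `betaq`,
#'   `betasort`, `distance_avg`, `correct_rank`, `constructive`); must sum
#'   to 1. Default: 90% constructive / 10% correct-ranking, emulating a
#'   human-like cohort in which most subjects hold idiosyncratic but
#'   self-consistent rankings and about one in ten ranks everything
#'   correctly.
#' @param alpha_range,gamma_range uniform sampling ranges for value-model
#'   agents' learning rate and inverse temperature.
#' @param constructive_gamma inverse temperature applied to a constructive
#'   agent's own subjective ranks (rank units; 3 gives ~95% consistency on
#'   subjectively adjacent pairs).
#' @param dispersion standard deviation of the Gaussian rank perturbation
#'   generating subjective orders (rank units; 0 = truth).
#' @param n_items,n_learn_blocks,n_test_blocks design geometry (8 items,
#'   4 learning blocks over the fixed 8-pair set, 10 testing blocks over
#'   all 28 pairs).
#' @param master_seed integer master seed.
#' @param n_subjects_meg MEG cohort size (default 27).
#' @param n_sensors synthetic sensor count (default 64).
#' @param sfreq sampling rate in Hz (default 100).
#' @param t_start,t_end epoch limits in seconds relative to stimulus onset.
#' @param noise_sd per-sensor Gaussian noise standard deviation.
#' @param amp named amplitudes of the three embedded effects (set an entry
#'   to 0 for a null effect).
#' @param windows named list of time windows (seconds) in which each
#'   effect is embedded; the subjective effect appears post-learning only.
#' @param meg_blocks,images_per_block sequential-task geometry (5 blocks of
#'   81 images, 80 judgments per block).
#' @return classed list `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 77L,
                          mix = c(constructive = 0.9, correct_rank = 0.1),
                          alpha_range = c(0.2, 0.6),
                          gamma_range = c(3, 8),
                          constructive_gamma = 3,
                          dispersion = 1.0,
                          n_items = 8L,
                          n_learn_blocks = 4L,
                          n_test_blocks = 10L,
                          master_seed = 1L,
                          n_subjects_meg = 27L,
                          n_sensors = 64L,
                          sfreq = 100,
                          t_start = -0.2, t_end = 1.2,
                          noise_sd = 1.0,
                          amp = c(lowlevel = 1, size = 1, subjective = 1),
                          windows = list(lowlevel = c(0.165, 0.290),
                                         size = c(0.240, 0.480),
                                         subjective = c(0.685, 0.775)),
                          meg_blocks = 5L, images_per_block = 81L) {
  if (abs(sum(mix) - 1) > 1e-8) stop_input("agent mix proportions must sum to 1")
  bad <- setdiff(names(mix), c(MODELS, "constructive"))
  if (length(bad)) stop_input("unknown agent type(s): %s", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample an idiosyncratic subjective ranking
#'
#' Perturbs the true ranks with independent Gaussian noise of the given
#' dispersion and re-sorts: dispersion 0 returns the truth, and the
#' expected Kendall tau to the truth decreases as dispersion grows.
#'
#' @param truth the true [rank_order()].
#' @param dispersion noise standard deviation in rank units (>= 0).
#' @param seed integer seed.
#' @return a [rank_order()] over the same items.
#' @export
sample_subjective_ranking <- function(truth, dispersion = 1.0, seed = 1L) {
  if (dispersion < 0) stop_input("dispersion must be >= 0")
  if (dispersion == 0) return(truth)
  with_seed(seed, {
    noisy <- seq_len(truth$n) + stats::rnorm(truth$n, 0, dispersion)
    rank_order(truth$items[order(noisy)])
  })
}

# subjective rank of the item sitting at each true rank position
subjective_rank_by_position <- function(truth, subjective) {
  unname(subjective$rank[truth$items])
}

#' Testing-phase choices of a constructive agent
#'
#' The agent answers every test pair from its own subjective ranking via
#' the logistic policy on subjective rank differences, so its errors
#' relative to the truth are consistent and transitive by construction.
#' Correctness in the returned table is still scored against the truth.
#'
#' @param subjective the agent's own [rank_order()].
#' @param gamma inverse temperature on subjective rank units.
#' @param truth the true [rank_order()] (labels and correctness).
#' @param test_sched a [build_test_schedule()] schedule.
#' @param seed integer seed.
#' @param subject_id identifier for the table.
#' @return a choice table (see [simulate_agent()]).
#' @export
constructive_agent_choices <- function(subjective, gamma = 3,
                                       truth = rank_order(),
                                       test_sched = build_test_schedule(seed = 1L),
                                       seed = 1L, subject_id = "s1") {
  if (gamma < 0) stop_input("gamma must be >= 0")
  v <- subjective_rank_by_position(truth, subjective)
  simulate_agent("correct_rank", gamma = gamma, rank = truth,
                 test_sched = test_sched, seed = seed,
                 subject_id = subject_id, values = v)
}

# largest-remainder apportionment of n subjects to the mix proportions
apportion_mix <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

#' Generate a synthetic behavioral cohort
#'
#' Assigns each subject an agent type per the configured mix, builds
#' per-subject learning and testing schedules, simulates all choices, and
#' records the hidden truth (agent, parameters, subjective order, seeds)
#' in a manifest for recovery-style validation.
#'
#' @param config a [cohort_config()].
#' @return list of class `behavioral_cohort`: `choices` (one combined
#'   choice table), `manifest` (per-subject data.frame), `subjective`
#'   (named list of subjective [rank_order()]s, NULL for value agents),
#'   `schedules` (per subject: `learn`, `test`), `truth`, `config`.
#' @export
generate_behavioral_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- rank_order(LETTERS[seq_len(config$n_items)])
  agents <- apportion_mix(config$mix, config$n_subjects)
  agents <- with_seed(derive_seed(config$master_seed, 0, 1), sample(agents))
  choices <- vector("list", config$n_subjects)
  schedules <- vector("list", config$n_subjects)
  subjective <- vector("list", config$n_subjects)
  man <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("s%03d", i)
    agent <- agents[i]
    ls <- build_learning_schedule(pair_set(), config$n_learn_blocks,
                                  seed = derive_seed(config$master_seed, i, 2))
    ts <- build_test_schedule(config$n_items, config$n_test_blocks,
                              seed = derive_seed(config$master_seed, i, 3))
    choice_seed <- derive_seed(config$master_seed, i, 4)
    par_seed <- derive_seed(config$master_seed, i, 6)
    alpha <- gamma <- NA_real_
    if (agent == "constructive") {
      subj <- sample_subjective_ranking(truth, config$dispersion,
                                        seed = derive_seed(config$master_seed, i, 5))
      subjective[[i]] <- subj
      gamma <- config$constructive_gamma
      tab <- constructive_agent_choices(subj, gamma, truth, ts,
                                        seed = choice_seed, subject_id = sid)
    } else {
      pars <- with_seed(par_seed, stats::runif(2))
      alpha <- config$alpha_range[1] + pars[1] * diff(config$alpha_range)
      gamma <- config$gamma_range[1] + pars[2] * diff(config$gamma_range)
      tab <- simulate_agent(agent, alpha = alpha, gamma = gamma, rank = truth,
                            learn_sched = ls, test_sched = ts,
                            seed = choice_seed, subject_id = sid)
    }
    choices[[i]] <- tab
    schedules[[i]] <- list(learn = ls, test = ts)
    man[[i]] <- data.frame(subject_id = sid, agent = agent, alpha = alpha,
                           gamma = gamma, choice_seed = choice_seed,
                           stringsAsFactors = FALSE)
  }
  ids <- vapply(man, function(m) m$subject_id, character(1))
  names(schedules) <- names(subjective) <- ids
  structure(list(choices = do.call(rbind, choices),
                 manifest = do.call(rbind, man),
                 subjective = subjective,
                 schedules = schedules,
                 truth = truth, config = config),
            class = "behavioral_cohort")
}

# Item coordinates whose pairwise pattern correlations realize the target
# RDM: the target correlation matrix is R = 1 - d / max(d) (unit diagonal;
# PSD for line-metric rank RDMs via the triangular kernel, and for cosine
# RDMs because 1 - d is then itself a Gram matrix). Any residual negative
# eigenvalues from non-embeddable structure are clamped to zero. With
# these coordinates, 1 - cor(patterns) is affine in the RDM, so a
# noiseless neural RDM correlates ~1 with its target.
embed_rdm_coords <- function(rdm) {
  R <- 1 - rdm / max(rdm)
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  keep <- ev > 1e-10
  eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), sum(keep))
}

# random semi-orthogonal mixing map (k coordinates -> n_sensors sensors),
# scaled so per-sensor signal variance is ~1 at unit amplitude
random_mixing_map <- function(k, n_sensors, seed) {
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(n_sensors * k), n_sensors, k)))
    sqrt(n_sensors) * t(Q)
  })
}

#' Generate a synthetic MEG-like cohort
#'
#' Per subject and phase, builds item x sensor x time pattern arrays as
#' time-windowed embeddings of model RDM geometry plus Gaussian sensor
#' noise: the low-level feature RDM and the (shared, truth-unrelated) size
#' RDM are embedded in both phases within their windows; the subject's own
#' subjective-rank RDM is embedded post-learning only, within the
#' configured subjective window. An RDM is converted to item coordinates
#' whose pairwise pattern correlations realize the RDM (so the 1 - Pearson
#' neural dissimilarity recovers it), then mixed into sensors through a
#' random orthogonal map fixed per subject and effect (shared across
#' phases). Also returns sequential-judgment choice tables for the
#' single-item stream task.
#'
#' @param config a [cohort_config()].
#' @param subjective optional named list of [rank_order()]s to reuse (e.g.
#'   from a behavioral cohort); sampled fresh when NULL.
#' @return list of class `meg_cohort`: `subjects` (each with `id`,
#'   `subjective`, `patterns$pre`, `patterns$post`), `time`,
#'   `lowlevel_rdm`, `size_rdm`, `size_ranks`, `choices`, `config`.
#' @export
generate_meg_cohort <- function(config = cohort_config(), subjective = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n_items <- config$n_items
  truth <- rank_order(LETTERS[seq_len(n_items)])
  time <- seq(config$t_start, config$t_end, by = 1 / config$sfreq)
  nt <- length(time)
  S <- config$n_sensors
  # shared structure: size ranks are a fixed permutation unrelated to the
  # learned order; low-level features are fixed synthetic vectors
  size_ranks <- with_seed(derive_seed(config$master_seed, 0, 10), sample(n_items))
  features <- with_seed(derive_seed(config$master_seed, 0, 11),
                        matrix(stats::rnorm(n_items * 24), n_items, 24))
  lowlevel_rdm <- feature_rdm(features)
  size_rdm <- model_rdm_from_ranks(size_ranks)
  in_window <- function(w) time >= w[1] & time <= w[2]
  w_low <- in_window(config$windows$lowlevel)
  w_size <- in_window(config$windows$size)
  w_subj <- in_window(config$windows$subjective)
  subjects <- vector("list", config$n_subjects_meg)
  choice_rows <- vector("list", config$n_subjects_meg)
  for (i in seq_len(config$n_subjects_meg)) {
    sid <- sprintf("m%03d", i)
    subj <- if (!is.null(subjective) && length(subjective) >= i && !is.null(subjective[[i]])) {
      subjective[[i]]
    } else {
      sample_subjective_ranking(truth, config$dispersion,
                                seed = derive_seed(config$master_seed, i, 20))
    }
    effects <- list(
      lowlevel = list(rdm = lowlevel_rdm, w = w_low, amp = config$amp[["lowlevel"]]),
      size = list(rdm = size_rdm, w = w_size, amp = config$amp[["size"]]),
      subjective = list(rdm = model_rdm_from_ranks(subj), w = w_subj,
                        amp = config$amp[["subjective"]])
    )
    pats <- lapply(seq_along(effects), function(e) {
      eff <- effects[[e]]
      if (eff$amp == 0) return(NULL)
      X <- embed_rdm_coords(eff$rdm)
      M <- random_mixing_map(ncol(X), S, derive_seed(config$master_seed, i, 30 + e))
      eff$amp * (X %*% M)
    })
    make_phase <- function(include_subjective, noise_seed) {
      with_seed(noise_seed, {
        arr <- array(stats::rnorm(n_items * S * nt, 0, config$noise_sd),
                     dim = c(n_items, S, nt))
        for (e in seq_along(effects)) {
          if (is.null(pats[[e]])) next
          if (names(effects)[e] == "subjective" && !include_subjective) next
          for (t in which(effects[[e]]$w)) arr[, , t] <- arr[, , t] + pats[[e]]
        }
        arr
      })
    }
    subjects[[i]] <- list(
      id = sid, subjective = subj,
      patterns = list(
        pre = make_phase(FALSE, derive_seed(config$master_seed, i, 40)),
        post = make_phase(TRUE, derive_seed(config$master_seed, i, 41))
      )
    )
    choice_rows[[i]] <- rbind(
      meg_stream_choices(size_ranks, config, sid, "meg_pre",
                         derive_seed(config$master_seed, i, 50)),
      meg_stream_choices(subjective_rank_by_position(truth, subj), config, sid,
                         "meg_post", derive_seed(config$master_seed, i, 51))
    )
  }
  names(subjects) <- vapply(subjects, `[[`, character(1), "id")
  structure(list(subjects = subjects, time = time,
                 lowlevel_rdm = lowlevel_rdm, size_rdm = size_rdm,
                 size_ranks = size_ranks,
                 choices = do.call(rbind, choice_rows),
                 config = config),
            class = "meg_cohort")
}

# sequential single-item stream -> pairwise judgments of consecutive items,
# answered by a logistic policy on the given rank values
meg_stream_choices <- function(values, config, subject_id, phase, seed) {
  sched <- build_meg_sequence(config$n_items, config$meg_blocks,
                              config$images_per_block,
                              seed = derive_seed(seed, 0, 0))
  with_seed(derive_seed(seed, 0, 1), {
    prev <- c(NA_integer_, sched$rank_a[-nrow(sched)])
    same_block <- c(FALSE, sched$block[-1] == sched$block[-nrow(sched)])
    judged <- which(same_block)
    cur <- sched$rank_a[judged]; prv <- prev[judged]
    p_cur <- softmax_choice_prob(values[cur], values[prv], config$constructive_gamma)
    chose_cur <- stats::runif(length(judged)) < p_cur
    chosen <- ifelse(chose_cur, cur, prv)
    other <- ifelse(chose_cur, prv, cur)
    data.frame(
      subject_id = subject_id, phase = phase,
      block = sched$block[judged], trial = sched$trial[judged],
      item_i = LETTERS[cur], item_j = LETTERS[prv],
      chosen_item = LETTERS[chosen],
      is_correct = as.integer(values[chosen] >= values[other]),
      stringsAsFactors = FALSE
    )
  })
}
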
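# Time-resolved representational similarity analysis: model and neural RDM
# construction, per-timepoint multiple regression, learning contrasts,
# sign-flip cluster permutation, and the cross-subject shuffle test of
# subject specificity.
#
# All RDMs are 8 x 8 (or n x n) symmetric dissimilarity matrices with zero
# diagonal, indexed by the canonical item order; their off-diagonal
# vectorization (upper triangle) is the unit of regression.

#' Rank-difference model RDM
#'
#' `d(i, j) = |rank_i - rank_j|` for a vector of item ranks (e.g. canonical
#' object-size ranks 1..8, or a subject's reconstructed subjective ranks).
#'
#' @param ranks numeric rank vector in canonical item order, or a
#'   [rank_order()] (ranks are taken in item-label order).
#' @return symmetric zero-diagonal matrix.
#' @export
model_rdm_from_ranks <- function(ranks) {
  if (inherits(ranks, "rank_order")) {
    ranks <- ranks$rank[sort(names(ranks$rank))]
  }
  abs(outer(as.numeric(ranks), as.numeric(ranks), "-"))
}

#' Cosine-dissimilarity model RDM from feature vectors
#'
#' `d(i, j) = 1 - cos(f_i, f_j)` over per-item feature vectors (e.g.
#' low-level visual features).
#'
#' @param features numeric matrix, one row per item.
#' @return symmetric zero-diagonal matrix.
#' @export
feature_rdm <- function(features) {
  features <- as.matrix(features)
  nrm <- sqrt(rowSums(features^2))
  if (any(nrm == 0)) stop_input("zero feature vector")
  cs <- (features %*% t(features)) / outer(nrm, nrm)
  d <- 1 - cs
  diag(d) <- 0
  d
}

#' Neural RDM from spatial activity patterns
#'
#' Dissimilarity between two items is 1 minus the Pearson correlation of
#' their sensor patterns.
#'
#' @param patterns numeric matrix, items x sensors (>= 2 sensors).
#' @return symmetric zero-diagonal matrix (entries in \[0, 2\]).
#' @export
neural_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2L) stop_input("need at least 2 sensors")
  v <- apply(patterns, 1, stats::var)
  if (any(v == 0)) stop_input("zero-variance pattern; dissimilarity undefined")
  d <- 1 - stats::cor(t(patterns))
  diag(d) <- 0
  d
}

#' Regress a neural RDM on model RDMs
#'
#' Ordinary least squares of the vectorized neural RDM on the vectorized
#' model RDMs, entered simultaneously with an intercept. Predictors are
#' z-scored across the off-diagonal entries so coefficients are
#' comparable across models; the response is left on its own scale.
#'
#' @param neural neural RDM (matrix).
#' @param models named list of model RDMs (same dimension).
#' @param zscore z-score the predictors (default TRUE).
#' @return named numeric vector of coefficients (one per model); attribute
#'   `"collinear"` flags rank deficiency among the predictors.
#' @export
rdm_regression <- function(neural, models, zscore = TRUE) {
  y <- rdm_vec(neural)
  X <- vapply(models, rdm_vec, numeric(length(y)))
  if (zscore) X <- scale(X)
  Xd <- cbind(1, X)
  qr_x <- qr(Xd)
  collinear <- qr_x$rank < ncol(Xd)
  beta <- qr.coef(qr_x, y)[-1]
  names(beta) <- names(models)
  structure(beta, collinear = collinear)
}

#' Time-resolved RSA betas for one pattern array
#'
#' Applies [neural_rdm()] + [rdm_regression()] at every timepoint.
#'
#' @param patterns array items x sensors x time.
#' @param models named list of model RDMs.
#' @return matrix predictors x time of regression coefficients.
#' @export
rsa_timecourse <- function(patterns, models) {
  nt <- dim(patterns)[3]
  out <- vapply(seq_len(nt), function(t) {
    as.numeric(rdm_regression(neural_rdm(patterns[, , t]), models))
  }, numeric(length(models)))
  rownames(out) <- names(models)
  out
}

#' RSA betas for a synthetic MEG cohort
#'
#' Runs the time-resolved regression for every subject and phase, with the
#' shared low-level and size predictors and each subject's own
#' subjective-rank RDM.
#'
#' @param cohort a cohort from [generate_meg_cohort()].
#' @return 4-d array \[subject, phase(pre, post), predictor(lowlevel, size,
#'   subjective), time\].
#' @export
rsa_cohort_betas <- function(cohort) {
  ns <- length(cohort$subjects)
  nt <- length(cohort$time)
  out <- array(NA_real_, dim = c(ns, 2, 3, nt),
               dimnames = list(names(cohort$subjects), c("pre", "post"),
                               c("lowlevel", "size", "subjective"), NULL))
  for (s in seq_len(ns)) {
    subj <- cohort$subjects[[s]]
    models <- list(lowlevel = cohort$lowlevel_rdm, size = cohort$size_rdm,
                   subjective = model_rdm_from_ranks(subj$subjective))
    for (ph in c("pre", "post")) {
      out[s, ph, , ] <- rsa_timecourse(subj$patterns[[ph]], models)
    }
  }
  out
}

#' Learning contrast of RSA betas
#'
#' The subjective-rank predictor is contrasted as post minus pre (isolating
#' learning-induced change against the pre-learning baseline); the
#' low-level and size predictors, which are expected in both phases, are
#' averaged across phases.
#'
#' @param betas array \[subject, phase, predictor, time\] from
#'   [rsa_cohort_betas()].
#' @return array \[subject, predictor, time\].
#' @export
learning_contrast <- function(betas) {
  if (!all(c("pre", "post") %in% dimnames(betas)[[2]])) {
    stop_input("betas must contain both pre and post phases")
  }
  preds <- dimnames(betas)[[3]]
  out <- array(NA_real_, dim = dim(betas)[c(1, 3, 4)],
               dimnames = c(dimnames(betas)[1], list(preds), dimnames(betas)[4]))
  for (p in preds) {
    out[, p, ] <- if (p == "subjective") {
      betas[, "post", p, ] - betas[, "pre", p, ]
    } else {
      (betas[, "pre", p, ] + betas[, "post", p, ]) / 2
    }
  }
  out
}

# maximal runs of same-sign suprathreshold t values -> clusters
find_clusters <- function(tvals, t_crit) {
  lab <- sign(tvals) * (abs(tvals) > t_crit)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep), function(k) {
               sum(tvals[starts[k]:ends[k]])
             }, numeric(1)))
}

#' Sign-flip cluster permutation test over time
#'
#' One-sample t statistics are computed at each timepoint across subjects;
#' clusters are maximal runs of same-sign timepoints exceeding the
#' two-sided cluster-defining threshold, with cluster mass the sum of t
#' values. The null distribution of the maximum absolute cluster mass is
#' built by randomly sign-flipping whole subjects; cluster p-values use the
#' add-one convention.
#'
#' @param x matrix subjects x time of per-subject effect time courses.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param cluster_p two-sided cluster-defining threshold (default 0.05).
#' @param seed integer seed.
#' @return list with `clusters` (data.frame start, end, mass, p), `tvals`,
#'   `t_crit`, and `null_max` (the permutation distribution).
#' @export
cluster_permutation_test <- function(x, n_perm = 1000L, cluster_p = 0.05,
                                     seed = 1L) {
  x <- as.matrix(x)
  ns <- nrow(x)
  if (ns < 5L) stop_input("need at least 5 subjects")
  if (n_perm < 100L) stop_input("n_perm must be >= 100")
  t_crit <- stats::qt(1 - cluster_p / 2, df = ns - 1)
  mu <- colMeans(x)
  ssq <- colSums(x^2)
  tstat <- function(m) {
    v <- (ssq - ns * m^2) / (ns - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / ns)
  }
  tvals <- tstat(mu)
  clusters <- find_clusters(tvals, t_crit)
  null_max <- with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE), n_perm, ns)
    mp <- (flips %*% x) / ns
    vapply(seq_len(n_perm), function(p) {
      cl <- find_clusters(tstat(mp[p, ]), t_crit)
      if (nrow(cl) == 0L) 0 else max(abs(cl$mass))
    }, numeric(1))
  })
  clusters$p <- vapply(clusters$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (1 + n_perm)
  }, numeric(1))
  list(clusters = clusters, tvals = tvals, t_crit = t_crit, null_max = null_max)
}

#' Average neural RDMs over a time window
#'
#' @param patterns array items x sensors x time.
#' @param time numeric time axis (seconds), length = dim 3.
#' @param window length-2 numeric interval (inclusive).
#' @return the mean of the per-timepoint neural RDMs inside the window.
#' @export
window_average_rdm <- function(patterns, time, window) {
  sel <- which(time >= window[1] & time <= window[2])
  if (length(sel) == 0L) stop_input("window contains no timepoints")
  Reduce(`+`, lapply(sel, function(t) neural_rdm(patterns[, , t]))) / length(sel)
}

#' Cross-subject shuffle test of subject-specific ranking codes
#'
#' The observed statistic is the group mean subjective-rank coefficient
#' from regressing each subject's window-averaged post-learning neural RDM
#' on the shared low-level and size RDMs plus the subject's own
#' subjective-rank RDM. The null reassigns the subjective-rank RDMs across
#' subjects at random (neural data untouched) and recomputes the group
#' mean; p is the add-one exceedance probability. A small p indicates the
#' neural patterns align with each subject's own ranking rather than with
#' other subjects' rankings.
#'
#' @param cohort a cohort from [generate_meg_cohort()].
#' @param window time interval (seconds) to average over.
#' @param n_perm number of shuffles.
#' @param seed integer seed.
#' @param phase which phase's patterns to use (default "post").
#' @return list with `observed`, `null`, `p`.
#' @export
subject_shuffle_test <- function(cohort, window, n_perm = 1000L, seed = 1L,
                                 phase = "post") {
  ns <- length(cohort$subjects)
  if (ns < 3L) stop_input("need at least 3 subjects")
  neural <- lapply(cohort$subjects, function(s) {
    window_average_rdm(s$patterns[[phase]], cohort$time, window)
  })
  subj_rdms <- lapply(cohort$subjects, function(s) {
    model_rdm_from_ranks(s$subjective)
  })
  mean_beta <- function(assign) {
    mean(vapply(seq_len(ns), function(s) {
      b <- rdm_regression(neural[[s]], list(lowlevel = cohort$lowlevel_rdm,
                                            size = cohort$size_rdm,
                                            subjective = subj_rdms[[assign[s]]]))
      b[["subjective"]]
    }, numeric(1)))
  }
  observed <- mean_beta(seq_len(ns))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) mean_beta(sample(ns)), numeric(1))
  })
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}
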
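test_that("Q-learning update matches hand-computed values and conserves total value", {
  q <- qlearning_update(numeric(8), 6, 1, alpha = 0.5)
  expect_equal(q[6], 0.5 * (5 / 7) / 2)   # 0.1785714...
  expect_equal(q[1], -0.5 * (5 / 7) / 2)
  expect_equal(sum(q), 0)
  # fixed point: bracket zero leaves state unchanged
  q2 <- numeric(8); q2[6] <- 5 / 14; q2[1] <- -5 / 14
  expect_equal(qlearning_update(q2, 6, 1, 0.3), q2)
  expect_error(qlearning_update(numeric(8), 2, 2, 0.5), "distinct")
  expect_error(qlearning_update(numeric(8), 2, 1, 1.5), "alpha")
})

test_that("Q-learning conserves the value sum over arbitrary schedules", {
  set.seed(11)
  q <- rnorm(8)
  total <- sum(q)
  for (t in 1:200) {
    pr <- sample(8, 2)
    q <- qlearning_update(q, pr[1], pr[2], runif(1, 0.05, 1))
    expect_equal(sum(q), total)
  }
})

test_that("softmax choice probability is the logistic in the value difference", {
  expect_equal(softmax_choice_prob(3, -1, 0), 0.5)
  expect_equal(softmax_choice_prob(1, 0, 1), 1 / (1 + exp(-1)))
  expect_equal(softmax_choice_prob(2, 1, 3) + softmax_choice_prob(1, 2, 3), 1)
  expect_gt(softmax_choice_prob(50, 0, 2), 1 - 1e-12)
  expect_error(softmax_choice_prob(1, 0, -1), "gamma")
})

test_that("Beta-Q update matches the printed shape-parameter arithmetic", {
  s <- betaq_update(beta_state(8), 4, 1, alpha = 0.5)  # D = 3/7, dV = 0
  expect_equal(s$u[4], 1 + 3 / 7)
  expect_equal(s$l[4], 1 - 0.5 * 3 / 7)
  expect_equal(s$u[1], 1 - 0.5 * 3 / 7)
  expect_equal(s$l[1], 1 + 3 / 7)
  expect_equal(s$u[2:3], c(1, 1))  # untouched items unchanged
  # orientation is resolved internally: (1, 4) behaves as (4, 1)
  expect_equal(betaq_update(beta_state(8), 1, 4, 0.5), s)
  # no mismatch, no movement: dV == D leaves the state fixed
  s2 <- beta_state(8)
  s2$u[4] <- 3; s2$l[4] <- 1          # V4 = 0.75
  v1 <- 0.75 - 3 / 7                  # choose V1 so dV equals D(4,1) = 3/7
  s2$u[1] <- 2 * v1; s2$l[1] <- 2 * (1 - v1)
  s3 <- betaq_update(s2, 4, 1, 0.7)
  expect_equal(s3$u, s2$u, tolerance = 1e-12)
  expect_equal(s3$l, s2$l, tolerance = 1e-12)
})

test_that("Beta-Q expected value moves toward the presented distance", {
  for (alpha in c(0.2, 0.5, 1)) {
    s <- beta_state(8)
    v0 <- s$u[6] / (s$u[6] + s$l[6])
    s1 <- betaq_update(s, 6, 2, alpha)   # D = 4/7 > dV = 0
    expect_gt(s1$u[6] / (s1$u[6] + s1$l[6]), v0)
    expect_lt(s1$u[2] / (s1$u[2] + s1$l[2]), v0)
  }
})

test_that("Betasort updates non-presented items by the three printed cases", {
  # between case: mean preserved, concentration raised
  s <- beta_state(8)
  out <- betasort_update(s, 6, 2, alpha = 0.5)  # all V = 0.5, ties -> between
  for (o in c(1, 3, 4, 5, 7, 8)) {
    expect_equal(out$u[o], 1.5)
    expect_equal(out$l[o], 1.5)
  }
  # low / high cases with dV = 0.4
  s <- beta_state(8)
  s$u[3] <- 7; s$l[3] <- 3     # Vm = 0.7
  s$u[2] <- 3; s$l[2] <- 7     # Vn = 0.3
  s$u[1] <- 1; s$l[1] <- 9     # Vo = 0.1 < Vn
  s$u[8] <- 9; s$l[8] <- 1     # Vo = 0.9 > Vm
  out <- betasort_update(s, 3, 2, alpha = 0.5)
  expect_equal(out$u[1], 1 + 0.4)        # low: Uo += dV
  expect_equal(out$l[1], 9 + 0.2)        # low: Lo += alpha * dV
  expect_equal(out$u[8], 9 + 0.2)        # high: mirrored with alpha on U
  expect_equal(out$l[8], 1 + 0.4)
  # presented pair follows the Beta-Q path exactly
  bq <- betaq_update(s, 3, 2, alpha = 0.5)
  expect_equal(out$u[c(2, 3)], bq$u[c(2, 3)])
  expect_equal(out$l[c(2, 3)], bq$l[c(2, 3)])
})

test_that("Beta comparison probability matches closed forms and sampling", {
  s <- list(u = c(2, 1), l = c(1, 2))
  expect_equal(beta_choice_prob(s, 1, 2), 5 / 6, tolerance = 1e-8)
  same <- list(u = c(3, 3), l = c(2, 2))
  expect_equal(beta_choice_prob(same, 1, 2), 0.5, tolerance = 1e-8)
  # complementarity
  expect_equal(beta_choice_prob(s, 1, 2) + beta_choice_prob(s, 2, 1), 1,
               tolerance = 1e-8)
  # Monte Carlo agrees within 3 standard errors
  n <- 40000L
  p_mc <- beta_choice_prob(s, 1, 2, method = "sampling", n_samples = n, seed = 9)
  se <- sqrt((5 / 6) * (1 / 6) / n)
  expect_lt(abs(p_mc - 5 / 6), 3 * se)
  expect_error(beta_choice_prob(s, 1, 2, method = "sampling", n_samples = 0), "n_samples")
})

test_that("distance-averaging values reproduce the worked example", {
  # default design: rank 8 sits in pairs with ranks 5 and 1, so its two
  # signed distances are +3 and +7 and they average to +5
  q <- distance_average_values()
  expect_equal(q[8], 5)
  # rank 1 sits in pairs with ranks 6 and 8
  expect_equal(q[1], -6)
  expect_equal(q[8], mean(c(8 - 5, 8 - 1)))
  # reversing rank orientation negates every value
  ps2 <- pair_set(9 - pair_set())
  expect_equal(distance_average_values(ps2), rev(-q))
  expect_error(distance_average_values(pair_set(rbind(c(1, 2))), n_items = 3),
               "no learned pair")
})

test_that("correct-ranking values are the true ranks", {
  expect_equal(correct_ranking_values(8), as.numeric(1:8))
  p_adj <- softmax_choice_prob(2, 1, 1.3)
  expect_equal(p_adj, stats::plogis(1.3))
})

test_that("simulated agents obey their choice policies at the limits", {
  ts <- build_test_schedule(seed = 5)
  # near-deterministic oracle: every choice correct
  co <- simulate_agent("correct_rank", gamma = 1000, test_sched = ts, seed = 1)
  expect_equal(nrow(co), 280L)
  expect_true(all(co$is_correct == 1))
  # gamma 0: chance accuracy within binomial tolerance
  co0 <- simulate_agent("qlearning", alpha = 0.3, gamma = 0, test_sched = ts, seed = 2)
  expect_lt(abs(mean(co0$is_correct) - 0.5), 4 * sqrt(0.25 / 280))
  # determinism
  a <- simulate_agent("betasort", alpha = 0.4, test_sched = ts, seed = 7)
  b <- simulate_agent("betasort", alpha = 0.4, test_sched = ts, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_agent("nope"), "arg")
})

test_that("value-model cohorts show distance and serial-position signatures", {
  # group simulation: positive symbolic-distance slope, U-shaped positions
  slopes <- numeric(12); ends <- numeric(12); mids <- numeric(12)
  for (i in 1:12) {
    co <- simulate_agent("qlearning", alpha = 0.35, gamma = 5,
                         learn_sched = build_learning_schedule(seed = 300 + i),
                         test_sched = build_test_schedule(seed = 400 + i),
                         seed = 500 + i)
    pa <- pair_accuracy(co)
    slopes[i] <- distance_effect_slope(pa)
    spc <- serial_position_curve(pa)
    ends[i] <- mean(spc[c(1, 8)]); mids[i] <- mean(spc[4:5])
  }
  expect_gt(mean(slopes), 0)
  expect_gt(mean(ends), mean(mids))  # U shape
})
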
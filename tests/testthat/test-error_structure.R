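test_that("majority tournaments direct pairs by majority choice", {
  t_all <- majority_tournament(fixture_pa(rep(1, 28)))
  expect_true(all(t_all$wins[lower.tri(t_all$wins)]))  # higher rank wins all
  expect_equal(sum(t_all$wins), 28L)
  vals <- rep(1, 28)
  pa <- fixture_pa(vals)
  k34 <- which(pa$lo == 3 & pa$hi == 4)
  vals[k34] <- 0
  t_rev <- majority_tournament(fixture_pa(vals))
  expect_true(t_rev$wins[3, 4])   # reversed edge
  expect_false(t_rev$wins[4, 3])
  # exact 0.5 resolves to the error direction and is flagged
  vals[k34] <- 0.5
  t_tie <- majority_tournament(fixture_pa(vals))
  expect_true(t_tie$wins[3, 4])
  expect_equal(t_tie$ties, 1L)
})

test_that("circular triad counts agree with known cases", {
  expect_equal(count_circular_triads(order_tournament(1:8)), 0L)
  rps <- structure(list(n_items = 3L,
                        wins = matrix(c(FALSE, FALSE, TRUE,
                                        TRUE, FALSE, FALSE,
                                        FALSE, TRUE, FALSE), 3, 3)),
                   class = "tournament")
  expect_equal(count_circular_triads(rps), 1L)
  expect_equal(count_circular_triads(rps, method = "scores"), 1L)
  # one reversed adjacent edge among 8 items: both routes agree
  t1 <- order_tournament(1:8)
  t1$wins[3, 4] <- TRUE; t1$wins[4, 3] <- FALSE
  expect_equal(count_circular_triads(t1),
               count_circular_triads(t1, method = "scores"))
  bad <- order_tournament(1:4); bad$wins[1, 2] <- bad$wins[2, 1] <- FALSE
  expect_error(count_circular_triads(bad), "complete")
})

test_that("enumeration and score-sequence routes agree on random tournaments", {
  for (i in 1:120) {
    n <- sample(4:8, 1)
    t <- random_tournament(n, seed = i)
    expect_equal(count_circular_triads(t, "enumeration"),
                 count_circular_triads(t, "scores"))
  }
})

test_that("maximum circular triads follow the parity closed form", {
  expect_equal(max_circular_triads(8), 20L)
  expect_equal(max_circular_triads(3), 1L)
  expect_equal(max_circular_triads(5), 5L)
  expect_equal(max_circular_triads(c(4, 6)), c(2L, 8L))
  expect_error(max_circular_triads(2), ">= 3")
})

test_that("self-consistency coefficient and categories follow the triad rule", {
  sc <- self_consistency(order_tournament(1:8))
  expect_equal(sc$coefficient, 1)
  expect_equal(sc$category, "correct")
  # transitive but wrong order: consistent_incorrect at coefficient 1
  sc2 <- self_consistency(order_tournament(c(2, 1, 3:8)))
  expect_equal(sc2$coefficient, 1)
  expect_equal(sc2$category, "consistent_incorrect")
  # a single 3-cycle: 1 - 1/20. Reversing the (1,3) edge makes {1,2,3}
  # cyclic (1 > 3, 3 > 2, 2 > 1) and nothing else.
  t1 <- order_tournament(1:8)
  t1$wins[1, 3] <- TRUE; t1$wins[3, 1] <- FALSE
  sc3 <- self_consistency(t1)
  expect_equal(sc3$n_circular, 1L)
  expect_equal(sc3$coefficient, 0.95)
  expect_equal(sc3$category, "inconsistent")
  # alternative all-triads denominator
  expect_equal(self_consistency(t1, nt = 56)$coefficient, 1 - 1 / 56)
})

test_that("coefficient is 1 exactly when the tournament is transitive", {
  for (i in 1:50) {
    t <- random_tournament(8, seed = 1000 + i)
    sc <- self_consistency(t)
    expect_true(sc$coefficient >= 0 && sc$coefficient <= 1)
    expect_equal(sc$coefficient == 1, count_circular_triads(t) == 0L)
  }
})

test_that("group self-consistency permutation test separates signal from noise", {
  # transitive subjects with idiosyncratic orders: observed 1, small p
  # (each accuracy vector mixes 0s and 1s, so shuffling breaks transitivity)
  template <- fixture_pa(rep(1, 28))
  pas <- lapply(1:10, function(i) {
    set.seed(i)
    perm <- sample(8)
    fixture_pa(as.numeric(perm[template$hi] > perm[template$lo]))
  })
  res <- permutation_test_consistency(pas, n_perm = 199, seed = 3)
  expect_equal(res$observed, 1)
  expect_lt(res$p, 0.05)
  expect_true(all(res$null <= 1))
  # determinism
  res2 <- permutation_test_consistency(pas, n_perm = 199, seed = 3)
  expect_identical(res, res2)
})

test_that("consistent-error pairs respect the threshold grid", {
  vals <- rep(1, 28); vals[c(3, 10)] <- c(0, 0.3)   # errors of 1.0 and 0.7
  pa <- fixture_pa(vals)
  expect_equal(nrow(consistent_error_pairs(pa, 1.0)), 1L)
  expect_equal(nrow(consistent_error_pairs(pa, 0.7)), 2L)
  expect_equal(nrow(consistent_error_pairs(pa, 0.8)), 1L)  # 0.7 error excluded
  expect_equal(nrow(consistent_error_pairs(fixture_pa(rep(1, 28)), 0.6)), 0L)
  expect_warning(consistent_error_pairs(pa, 0.75), "grid")
})

test_that("cohort consistent-error counts are monotone in the threshold", {
  pas <- list(fixture_pa(c(rep(1, 27), 0)),       # one total-error pair
              fixture_pa(c(rep(1, 27), 0.3)),     # one 0.7-error pair
              fixture_pa(rep(1, 28)))             # clean subject
  cec <- cohort_consistency_counts(pas)
  expect_equal(cec$count[cec$threshold == 0.6], 2L)
  expect_equal(cec$count[cec$threshold == 1.0], 1L)
  expect_true(all(diff(cec$count) <= 0))
  expect_equal(cec$proportion, cec$count / 3)
})

test_that("error-consistency score averages majority-error pairs", {
  vals <- rep(1, 28); vals[5] <- 0
  expect_equal(error_consistency_score(fixture_pa(vals)), 1)
  vals[c(5, 6)] <- c(0.1, 0.3)   # errors 0.9 and 0.7
  expect_equal(error_consistency_score(fixture_pa(vals)), 0.8)
  expect_true(is.na(error_consistency_score(fixture_pa(rep(1, 28)))))
})

test_that("Beta shape classification recovers generating regimes", {
  set.seed(4)
  f_uni <- fit_beta(rbeta(500, 2, 2))
  expect_equal(f_uni$category, "unimodal")
  f_bi <- fit_beta(rbeta(500, 0.3, 0.3))
  expect_equal(f_bi$category, "bimodal")
  expect_lt(abs(f_bi$alpha_hat - 0.3), 0.12)
  # classification rule applied to given shapes
  expect_equal(beta_category(0.5, 0.5), "bimodal")
  expect_equal(beta_category(2, 0.5), "high_accuracy")
  expect_equal(beta_category(0.5, 2), "low_accuracy")
  expect_equal(beta_category(3, 3), "unimodal")
  # degenerate input flagged, not fatal
  f_deg <- fit_beta(rep(0.9, 30))
  expect_true(f_deg$degenerate)
  expect_equal(f_deg$category, "high_accuracy")
  expect_error(fit_beta(c(0.2, 0.4)), "at least 5")
})
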
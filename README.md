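# tinfer

Few-shot transitive inference: value-learning choice models, ranking
self-consistency statistics, HodgeRank reconstruction of subjective
rankings, and time-resolved representational similarity analysis (RSA),
with a fully seeded synthetic-cohort generator.

## The scientific problem

In a transitive-inference task, people learn a hidden ranking of 8 items
(A < B < ... < H) from only a few pairwise observations — here, a fixed set
of eight pairs, each seen four times — and are then tested without feedback
on all 28 possible pairs, ten times each. Group averages show the classic
signatures of relational learning (accuracy rises with the rank distance of
a pair; items at the ends of the list are judged best), and these are well
captured by incremental value-learning models. But at the individual level,
errors are not noise: many subjects repeat the *same* wrong judgment on a
pair across essentially all of its trials, while remaining globally
transitive. That pattern is what a learner would produce if it had committed
to a single, idiosyncratic, internally consistent subjective ranking that
happens to differ from the truth — and it is exactly what independent-value
learners cannot produce. This package implements both accounts and every
statistic needed to tell them apart, plus a time-resolved RSA pipeline that
asks whether sensor-level neural patterns realign with each subject's *own*
reconstructed ranking after learning.

## Models and statistics

Five agents generate (and are fitted to) testing-phase choices; learning
uses the signed normalized rank distance `D(m, n) = (m − n)/7` of each
presented pair:

- **Q-learning** — delta rule on item values,
  `Qm ← Qm + α[D(m,n) − (Qm − Qn)]/2` (and symmetrically for `Qn`), with a
  logistic choice policy `p(i ≻ j) = 1/(1 + e^{−γ(Qi−Qj)})`.
- **Beta-Q** — each item's value is a Beta(U, L) distribution; shapes move
  by the mismatch between `D` and the expected-value difference; choices
  compare independent draws, `p(i ≻ j) = P(Xi > Xj)` (evaluated exactly).
- **Betasort** — Beta-Q plus updates of every *non-presented* item
  (confirmed items concentrate at fixed mean; items below/above the pair
  are shifted).
- **Distance-averaging** — a non-learning baseline: each item's value is
  the mean of its raw signed distances over the learned pairs containing it
  (distances +3 and +7 average to +5).
- **Correct-ranking** — an oracle baseline: `Qi = ri`.

Per-subject statistics: 28-pair accuracy matrices; serial-position curves
and symbolic-distance slopes; Beta-shape classification of cross-subject
accuracy distributions (`α, β` vs 1: unimodal / high / low / bimodal);
consistent-error counts at thresholds 0.6–1.0; the self-consistency
coefficient `1 − Nd/NT` (circular triads `Nd` out of the theoretical
maximum `NT`, 20 for 8 items) with a within-subject permutation test;
HodgeRank least-squares reconstruction of each subject's global ranking
from ±1-coded preferences (`min_s Σ (s_i − s_j − Ŷij)²`); and Kendall-τ
inter-subject similarity. The RSA module builds neural RDMs
(1 − Pearson over sensors), regresses them at every timepoint on three
model RDMs (low-level features, canonical size ranks, the subject's own
subjective ranks), contrasts post- vs pre-learning, and tests effects with
sign-flip cluster permutation plus a cross-subject shuffle test of subject
specificity.

## Worked example

A "constructive" agent holds its own subjective ranking and answers every
test pair from it:

```r
library(tinfer)
truth <- rank_order()                                     # A < B < ... < H
subj  <- sample_subjective_ranking(truth, dispersion = 1, seed = 42)
print(subj)
#> Rank order (1 = lowest): B < A < C < D < E < F < H < G

choices <- constructive_agent_choices(subj, gamma = 3, truth = truth,
                                      test_sched = build_test_schedule(seed = 1),
                                      seed = 2, subject_id = "demo")
pa <- pair_accuracy(choices, truth)
overall_accuracy(pa)                    # 0.932
distance_effect_slope(pa)               # 0.044

sc <- self_consistency(majority_tournament(pa))
sc$coefficient; sc$category             # 1, "consistent_incorrect"

h <- hodgerank(preference_matrix(choices, items = truth$items))
print(h$order)
#> Rank order (1 = lowest): B < A < C < D < E < F < H < G
kendall_tau(h$order, subj)              # 1
kendall_tau(h$order, truth)             # 0.857
```

The agent is 93% "accurate" and shows a positive distance effect, yet its
two consistent errors (A/B and G/H swapped) make it *consistent but
incorrect*: zero circular triads, self-consistency exactly 1, and HodgeRank
recovers its private order — not the truth — from the raw choices.
`run_pipeline(cohort_config(...))` applies the whole battery (exclusions,
accuracy metrics, Beta classification, consistency categories and
permutation test, ranking reconstruction, similarity) to a synthetic
cohort; `generate_meg_cohort()` + `rsa_cohort_betas()` +
`cluster_permutation_test()` / `subject_shuffle_test()` do the same for the
sensor-pattern analyses.

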
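---
title: "Models, consistency statistics, and synthetic cohorts in tinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, consistency statistics, and synthetic cohorts in tinfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinfer)
```

## The task and its data structure

`tinfer` analyzes few-shot transitive inference over 8 ranked items. The
design is fixed: a learning phase of 4 blocks over a fixed set of 8 pairs
(each pair once per block, order randomized within block), then a testing
phase of 10 blocks over all `choose(8, 2) = 28` pairs, without feedback.
The learned-pair set, expressed in rank positions, is
(1,6), (2,3), (2,5), (3,7), (4,6), (4,7), (5,8), (1,8): every position
occurs in exactly two pairs and the rank distances span 1–7. One pair,
(2,3), is rank-adjacent; the printed pair list is authoritative and
"non-adjacency" is treated as a description of the set's character, not a
constraint the code enforces.

All learning operates in rank space. Ranks are 1-based with 1 = lowest;
pairs are stored unordered and oriented at use time. The teaching signal
is the signed normalized distance `D(m, n) = (m − n)/(n − 1 items)`, i.e.
`(m − n)/7` for 8 items.

## The five agents

**Q-learning.** Both presented items move toward the observed distance,
reading pre-update values, so the update conserves the value sum exactly:
this conservation is tested over arbitrary random schedules. Free
parameters: learning rate `α ∈ (0, 1]` and inverse temperature `γ ≥ 0`
of the logistic test policy. Values start at 0.

**Beta-Q.** Item values are Beta(U, L) distributions starting at
Beta(1, 1). The four shape increments for a presented pair read pre-update
expected values `V = U/(U + L)`. Two numerical choices matter here:

- The printed increments can drive shapes non-positive over long runs, so
  shapes are clamped at `ε = 1e−6` after every update — the Beta density
  requires positive shapes.
- The choice probability `P(Xi > Xj)` is a nested Beta integral. We
  evaluate it on the probability scale of `Xi`, as
  `∫₀¹ F_j(Q_i(u)) du` with `F` and `Q` the Beta CDF and quantile
  function. This is analytically identical to the density-times-CDF form
  but its integrand is bounded in [0, 1] for *any* shape values, whereas
  the raw density explodes at clamped shapes and breaks adaptive
  quadrature. Accuracy is checked against the closed form
  `P = 5/6` for Beta(2,1) vs Beta(1,2) and against Monte-Carlo sampling.

**Betasort.** Extends Beta-Q to non-presented items, with the case of each
bystander item (between the pair, below it, above it) decided on
pre-update expected values and the whole update applied atomically. Ties
(`Vo` exactly equal to `Vn` or `Vm`) fall into the "between" case, since
strict inequalities leave them undefined. With the pair oriented `m > n`,
`ΔV ≥ 0` early in learning, and the printed below/above updates are
implemented exactly as printed.

**Distance-averaging** and **correct-ranking** are non-learning baselines.
Note the deliberate units asymmetry: the learning models consume
*normalized* distances (range [−1, 1]) while distance-averaging uses *raw*
signed rank differences, matching its worked example (distances +3 and +7
average to a value of +5). Both conventions are visible in the API
(`signed_rank_distance()` vs `distance_average_values()`).

## Likelihood and fitting

Learning involves no responses, so the end-of-learning state is a
deterministic function of (model, α, learning schedule) and the test-phase
likelihood has no latent variables. The likelihood reduces to per-pair
sufficient statistics (counts of higher-item choices), with probabilities
floored at `1e−12`; at `γ = 0` it equals `n log 2` exactly.

Fitting is bounded maximum likelihood: `α ∈ [1e−3, 1]`,
`γ ∈ [0, 100]`. The γ ceiling is a practical choice — the logistic
saturates long before 100 at the value scales these models produce, and an
unbounded γ destabilizes near-perfect subjects. Optimization uses
L-BFGS-B from 10 Latin-hypercube starts (deterministic given a seed); the
best restart wins and a convergence flag is recorded rather than thrown.
The Beta models fit α alone (their sampling policy has no temperature);
the baselines fit γ alone. Parameter recovery at the design's scale
(40 subjects, 32 learning / 280 testing trials, truth α = 0.3, γ = 5) is
exercised in the acceptance suite with tolerances of ±0.1 on mean α̂ and
±20% on mean γ̂.

## Consistency statistics

Pair accuracies (10 trials per pair) define a majority tournament:
accuracy > 0.5 directs a pair toward the truly higher item. An exact 0.5
is resolved toward the *error* direction and flagged, because the majority
rule defines a pair as correct only strictly above 50%. Circular triads
are counted two ways — direct enumeration of all 3-subsets (the default,
and the definition) and the score-sequence identity
`C(n,3) − Σ C(wins_i, 2)` — and the two routes are proven equal on 1,000
random tournaments. The self-consistency coefficient is `1 − Nd/NT` with
`NT` the parity-dependent maximum (`(n³−n)/24` odd, `(n³−4n)/24` even; 20
for 8 items). An all-triads denominator (56 for 8 items) can be supplied
via the `nt` argument for comparison with the uncorrected convention.
Categories: *correct* (tournament equals the true order),
*consistent-incorrect* (transitive, different order), *inconsistent*
(any circular triad — one cycle suffices, since longer cycles always
contain a 3-cycle).

The group permutation test shuffles each subject's 28 accuracy values
across pair positions (preserving the per-subject multiset), rebuilds
tournaments, and compares the mean coefficient against the shuffled null
with the add-one convention `p = (1 + #{null ≥ obs})/(1 + n_perm)`. The
group aggregator (mean) is our choice; the internal coefficient
computation uses the score-sequence identity for speed.

Beta-distribution classification of cross-subject accuracies uses maximum
likelihood (`fitdistrplus`) with a method-of-moments fallback, after the
uniform boundary shrink `x′ = (x(N−1) + 0.5)/N` — exact 0s and 1s are
common at 10 trials per pair and break the likelihood. Shapes exactly 1
classify to the non-strict side (`α ≤ 1` and `β ≤ 1` → bimodal); inputs
with no spread at all are flagged degenerate and classified from their
mean only.

## Ranking reconstruction

HodgeRank solves `min_s Σ (s_i − s_j − Ŷij)²` over observed pairs, with
`Ŷij` the mean ±1 trial code. On the complete test design this equals the
row mean of the preference matrix (asserted to `1e−10`); the general
solver goes through the graph-Laplacian pseudoinverse so incomplete but
connected comparison graphs also work, and disconnected graphs fail
loudly naming the components. Scores are centered to sum zero (the
objective is shift-invariant); exact score ties are broken by item label
and counted in a `ties` field. Inter-subject similarity is Kendall's τ
between reconstructed orders, for all subject pairs. In `run_pipeline()`
rankings are reconstructed for every included subject — for subjects whose
tournament already matches the truth the reconstruction simply returns it.

## The synthetic cohorts

The generators define the study conditions; they are not tuning dials.
Behavioral defaults: 77 subjects; agent mix 90% *constructive* / 10%
correct-ranking, emulating a cohort in which most members hold
idiosyncratic but self-consistent rankings and roughly one in ten ranks
everything correctly; subjective orders drawn by perturbing true ranks
with Gaussian noise of dispersion 1.0 (rank units) and re-sorting;
constructive inverse temperature 3 on subjective rank units (≈95% choice
consistency for subjectively adjacent pairs). Value-agent cohorts draw
α ~ U(0.2, 0.6) and γ ~ U(3, 8), a range that matches the human-scale
accuracy regime. Gaussian rank perturbation was chosen over a Mallows
model for simplicity and transparent dispersion control; it does not
capture position-dependent confusability (middle items are not
specifically harder to place), which is a known simplification.

Every stochastic operation takes an explicit seed; cohort functions derive
per-subject, per-stage sub-seeds from the master seed with a fixed affine
splitter, so two runs of any generator are byte-identical.

MEG-like cohorts (default 27 subjects, 64 sensors, 100 Hz, epochs −0.2 to
1.2 s, unit noise SD) embed three effects as time-windowed pattern
components: a shared low-level feature RDM (window 165–290 ms, both
phases), a shared size-rank RDM from a fixed permutation *unrelated* to
the learned order (240–480 ms, both phases), and each subject's own
subjective-rank RDM (685–775 ms, post-learning only). The windows are
configuration, not claims about latencies. The embedding construction
deserves a note: classical MDS coordinates of a rank-difference RDM are
essentially one-dimensional (the items lie on a line), which makes
noiseless patterns collinear and saturates the 1 − Pearson dissimilarity
at {0, 2}. We instead build item coordinates whose pairwise *correlations*
realize the RDM: the target correlation matrix is `R = 1 − d/max(d)`,
which is positive semi-definite for line-metric RDMs (triangular kernel)
and for cosine RDMs (then `1 − d` is itself a Gram matrix); residual
negative eigenvalues from non-embeddable structure are clamped to zero.
Coordinates are mixed into sensors through a random semi-orthogonal map
fixed per subject and effect (shared across phases), scaled to unit
per-sensor signal variance at amplitude 1. With near-zero noise the
neural RDM inside an effect's window then correlates ≈1 with its target,
which is the property the round-trip tests assert.

What the generator does *not* emulate: evoked-response morphology,
sensor covariance and channel noise structure, artifacts, real Neuromag
geometry (hence no searchlight), or any coupling between behavioral
accuracy and pattern SNR. Passing round-trip tests therefore demonstrates
the correctness and calibration of the analysis chain, not properties of
real recordings.

## RSA numerical choices

Neural RDMs are `1 − Pearson` across sensors per timepoint; zero-variance
patterns are an error rather than silently NA. Regression enters the three
model RDMs simultaneously with an intercept, z-scoring predictors across
the 28 off-diagonal entries so coefficients are comparable across models
(the response is left unscaled, so coefficient magnitude tracks neural
effect size); rank-deficient designs are flagged, not dropped. The
learning contrast is post − pre for the subjective predictor and the
phase mean for the two shared predictors. Cluster inference uses maximal
same-sign runs of timepoints exceeding a two-sided `p < 0.05`
cluster-defining t threshold, cluster mass = summed t, and a sign-flip
null over subjects summarized by the maximum absolute cluster mass, with
add-one p-values. The subject-shuffle test regresses window-averaged
post-learning neural RDMs on the shared predictors plus shuffled
subjective RDM assignments; when all subjects hold the same ranking the
shuffle is a no-op and the test is powerless by construction — a property
the suite asserts rather than hides.

## Problem sizes used by the test and acceptance suites

The suites run at sizes chosen to make every stochastic assertion stable
under its fixed seed while keeping a full run in the minutes range on one
CPU: 1,000 random tournaments for the dual-route triad identity;
exhaustive tournament search for n = 3..5; 50 random orders for exact
HodgeRank recovery; 40 subjects for parameter recovery; 77 constructive
vs 69 Q-learning subjects for the dissociation battery; 20 MEG subjects
at full default geometry with 1,000 permutations for the RSA round trip;
and 200 replicate cohorts at reduced geometry (6–8 subjects, ~100
permutations) for the two calibration checks, asserted with deliberately
coarse uniformity bounds.

## Known limitations

- The Betasort variant implemented is the simplified one defined by its
  printed update rules; the original algorithm's relaxation/recall
  mechanics are out of scope.
- Group-level inferential machinery beyond what the analyses need
  (repeated-measures ANOVA, mixed-effects distance models) is not
  provided; `run_pipeline()` reports means and a t statistic on slopes.
- Incomplete comparison graphs are supported by the HodgeRank solver but
  not by the tournament statistics, which require a complete design.
- The pair-level Beta classification assumes exchangeable subjects; it is
  not a mixture model and does not estimate per-subject membership.
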
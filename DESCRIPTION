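Package: tinfer
Title: Few-Shot Transitive Inference: Choice Models, Ranking Consistency,
    and Time-Resolved Representational Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers infer a global ranking of
    items from a handful of pairwise observations. Implements five
    value-learning and choice models for transitive inference
    (Q-learning, Beta-Q, Betasort, distance-averaging, correct-ranking),
    maximum-likelihood fitting of trial-by-trial choices, behavioral
    signature metrics (serial-position and symbolic-distance effects,
    pair accuracy), circular-triad self-consistency statistics with a
    permutation test, HodgeRank reconstruction of subjective rankings
    from pairwise judgments, inter-subject ranking similarity, and a
    time-resolved representational similarity analysis (RSA) with
    sign-flip cluster permutation and subject-shuffle specificity tests.
    Ships a seeded synthetic-cohort generator (behavioral and MEG-like
    sensor patterns) so the full pipeline runs end to end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    lhs,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
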
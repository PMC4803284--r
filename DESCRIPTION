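Package: chordexpect
Title: Stochastic Models of Harmonic Expectancy in Chord Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational-model-based analysis of harmonic
    expectancy: how well the final chord of a short major-triad sequence is
    judged to belong to its context. Implements six stochastic expectancy
    models (pitch-based, first- and second-order Markov, and Bayesian
    updating/switching models with a hidden tonal reference), their fitting
    by discrete coordinate descent on a rating-weighted cross-entropy,
    held-out and cross-validated model comparison with exact sign tests,
    pre-modelling behavioral statistics (Kruskal-Wallis, Friedman,
    non-metric multidimensional scaling, complete-link clustering), and a
    synthetic-rating generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vegan,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
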
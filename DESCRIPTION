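Package: relpred
Title: Predication-Based Semantic Relatedness and Literality-Decision Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the semantic relationship between the two
    keywords of nominal "x is a y" statements in a word-embedding space and
    for analysing literality-decision behaviour. Implements plain cosine
    similarity (Cos) and the predication-based Relatedness score (the
    k1-k2-m extension of Kintsch's predication algorithm, default 5-5-4500),
    exhaustive greedy matching of literal statements to metaphors on
    normalized lexical covariates, reaction-time trimming, mixed-effects
    model ladders with AIC bookkeeping and Satterthwaite degrees of freedom,
    pairwise literality-advantage summaries, and a synthetic-data module
    (clustered embedding lexicons, matched statement sets, and trial-level
    reaction-time/accuracy data from a generative mixed model) so the whole
    pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
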
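Package: iclsim
Title: Interplay of In-Context and In-Weight Learning in Small Sequence Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A simulation framework for studying how in-context learning (ICL)
    and in-weight learning (IWL) interact within a single attention-based
    sequence model. Provides seeded generators for two task families used in
    human curriculum-learning studies (two-dimensional category learning with
    rule-like or 45-degree-rotated boundaries, and a compositional 5x5
    color-animal coordinate grid), token encodings, a compact decoder-only
    transformer with hand-written backpropagation, metalearning and
    task-specific training loops, frozen-weight few-shot evaluation, retention
    tests with context removed, attention-ablation sweeps for the
    flexibility-retention tradeoff, and curriculum-by-rotation effect
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
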
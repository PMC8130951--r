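Package: recallkit
Title: Scoring and Nonparametric Analysis of Free-Recall Memory Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring free-recall response sheets against an ordered
    target word list and analysing three-arm repeated-measures memory-training
    trials. Written entries are fuzzily matched to targets with a one-to-one
    maximum-similarity assignment, classified into a four-category error
    taxonomy (correct, near miss, insertion, null, with removal tracking
    across timepoints), and summarised by a positional-distance Sequence
    Index. Group-level analysis uses the Friedman test with Nemenyi post-hoc
    comparisons and Kendall's W effect sizes, plus an improvement-to-perfect-
    recall ratio analysis. A synthetic cohort generator (card-deck block
    randomization, compound-word lists, logistic recall model with a
    configurable error mixture) makes the whole pipeline runnable and
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
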
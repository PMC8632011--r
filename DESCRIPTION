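Package: entrate
Title: Entropy and Channel-Capacity Analysis of Artificial Grammar Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Information-theoretic tools for rule-induction experiments with
    finite artificial grammars. Builds XXY repetition and aXb
    nonadjacent-dependency grammar designs with their familiarization
    sequences and yes/no test batteries; computes positional bigram/trigram
    Shannon entropies and the grammar entropy total (bits/symbol); derives
    source bit rates (bits/second) from timing schedules and the speed-up
    factors that equate bit rates across entropy conditions; simulates
    learner cohorts under a channel-capacity encoding-mode model
    (item-bound versus category-based generalization); and scores the
    resulting judgments with accuracy summaries, empirical-logit
    transforms, Cohen's d, one-sample Wilcoxon signed-rank tests, d-prime,
    acceptance-trend tests, and maximum-likelihood recovery of the
    capacity model's parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
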
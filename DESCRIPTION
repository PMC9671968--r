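Package: lineagehmm
Title: Hidden Markov Models on Single-Cell Lineage Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies heritable phenotypic heterogeneity in single-cell
    lineage trees with a tree-structured hidden Markov model. Cells carry
    Bernoulli fate outcomes and gamma-distributed cell-cycle phase (or
    whole-lifetime) durations; hidden states are inherited from mother to
    daughter through a shared transition matrix. Provides exact upward and
    downward recursions with normalizing-factor scaling, tree Viterbi
    decoding, Baum-Welch fitting with censorship-corrected emission
    estimators (right-censored gamma maximum likelihood, shared shape and
    optionally ordered scales across treatment conditions), BIC and
    masked-cell cross-validation for choosing the number of states, a
    branching-process generator of synthetic lineage populations with
    experiment-window censorship, and benchmarking utilities including an
    analytic lineage-free baseline classifier.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
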
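Package: hierseq
Title: Hierarchical Structure Discovery and Complexity Metrics for Behavioral Sequences
Version: 0.1.0
Authors@R:
    person("Derry", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and measures hierarchical structure in ethogram-coded
    behavioral sequences. Induces a context-free grammar per sequence with the
    Sequitur lossless compression algorithm, encodes each grammar rule as a
    binary tree-shape string, and computes six hierarchical-complexity
    measures (nesting depth, chunk count, phrase length, structural entropy,
    Gini coefficient of non-terminal positions, and terminal:non-terminal
    ratio). Provides length-matched i.i.d. and first-order Markov control
    simulators, shared-versus-unique rule-structure classification across
    groups, and Bayesian group comparison with Poisson and zero-inflated beta
    outcome models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
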
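Package: dnafcm
Title: Multiple Competing Finite-Context Models for DNA Sequences
Version: 1.0.0
Authors@R:
    person("dnafcm", "developers", email = "dnafcm@users.noreply.github.com",
           role = c("aut", "cre"))
Description: Describes whole DNA sequences with adaptive order-k
    finite-context (Markov) models: a generalized pseudocount probability
    estimator, inverted-repeat-aware count updates, block-wise competition
    among models of different orders with an adaptively coded side channel,
    an arithmetic coder producing a lossless bitstream from the same
    estimates, and per-base information-content and per-block model-depth
    profiles. Includes a seeded synthetic-sequence generator (iid, Markov,
    direct and inverted repeats) for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
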
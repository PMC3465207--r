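Package: clingram
Title: Unsupervised Grammar Induction for Clinical Report Sublanguage
Version: 0.1.0
Authors@R:
    person("clingram", "maintainers", email = "clingram@example.org",
           role = c("aut", "cre"))
Description: Induces a context-free grammar for the sublanguage of a genre of
    clinical reports from an unannotated corpus of tagged sentences
    (part-of-speech tags plus semantic-class tags). Starting from a trivial
    grammar with one production per unique training sentence, a greedy search
    repeatedly applies combine and merge operators so as to minimise an
    f-weighted encoding cost of the grammar plus all sentence derivations
    (a minimum-description-length criterion). Production probabilities are
    then estimated from the same unannotated corpus by hard (Viterbi)
    expectation-maximisation, and novel sentences are parsed with a
    probabilistic chart parser that handles arbitrary-length right-hand
    sides without binarisation. Includes unlabeled-bracketing evaluation,
    a synthetic clinical-like corpus generator with gold trees, and a
    command-line interface tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
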
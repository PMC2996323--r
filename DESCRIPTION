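Package: gerpr
Title: Rejected-Substitution Constraint Scoring and Constrained Element
    Detection in Multiple Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies evolutionary constraint at individual columns of a
    reference-projected multiple sequence alignment in units of rejected
    substitutions (RS): the neutral substitution rate expected from a supplied
    phylogeny minus the rate estimated by maximum-likelihood rescaling of that
    phylogeny under the HKY85 model, computed with Felsenstein's pruning
    algorithm.  Contiguous high-scoring segments are aggregated into
    constrained elements ranked by empirical p-values obtained by dynamic
    programming over a discretized null score distribution, with greedy
    non-overlapping selection and a shuffle-based false-positive-rate
    estimate.  Includes a seeded alignment simulator with known ground truth,
    readers and writers for MAF, newick, BED and rates-track formats, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
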
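Package: tcoa
Title: Target Control of Directed Networks with Objectives-Guided
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds driver-node sets that render a chosen set of target
    nodes structurally controllable in a directed network while
    maximising overlap with a pre-selected constraint set, such as
    approved drug-target genes in a protein-protein interaction network.
    Implements iterated bipartite maximum matching (the "linking and
    dynamic graph"), target control tree construction with per-node
    controllable target subspaces, integer-programming driver selection
    by branch and bound, and Metropolis-Hastings sampling over maximum
    matchings with per-node control capacity.  Ships full-control and
    target-control baselines, a numeric rank-condition oracle for
    verifying structural target controllability, synthetic network
    generators, and controllability-surface evaluation over target and
    constraint fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
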
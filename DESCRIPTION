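Package: cophyrec
Title: Cophylogeny Reconciliation with Exact Enumeration of All Optimal
    Event Histories
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Parsimony reconciliation of a parasite (or gene) phylogeny
    against a host (or species) phylogeny under the
    cospeciation/duplication/host-switch/loss event model with an
    arbitrary real-valued cost vector.  A dynamic program over the tree
    pair finds the optimal cost, counts all co-optimal reconciliations
    exactly in arbitrary precision, and enumerates them one by one with
    linear delay from a compact solution graph.  Each reconciliation can
    be tested for time feasibility (acyclicity of the induced temporal
    constraints on host speciations), grouped into event-count classes,
    and re-solved under a bound on the host-tree distance a switch may
    span, including the scan procedures that locate the smallest useful
    bound and the largest bound admitting a time-feasible optimum.
    Input is a host/parasite Nexus dialect or plain Newick files plus a
    leaf-association table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
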
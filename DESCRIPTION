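Package: synflux
Title: Optimal Selective Drug Combinations on Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based design of synergistic drug combinations on
    stoichiometric metabolic networks. Finds the subset of a drug catalog that
    blocks a chosen objective reaction while minimizing a side-effect score
    (number of newly stopped reactions plus a weighted penalty for
    non-metabolic targets), by reformulating the bilevel flux-balance program
    into a single mixed-integer linear program via LP strong duality with
    exact big-M linearization. Includes hierarchical enumeration of suboptimal
    combinations through exclusion cuts, a two-network selectivity variant
    (inhibit a target cell while sparing a reference cell), an
    additional-target screen, an independent LP-based blocking oracle used for
    verification, and downstream synergy characterization (classification,
    Jaccard distances, cluster trees, drug proximity networks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    reticulate,
    jsonlite,
    xml2,
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Python (>= 3.8) with numpy and scipy (>= 1.9) on PATH
Config/testthat/edition: 3
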
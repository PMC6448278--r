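Package: protoworld
Title: Spatial Monte Carlo Simulation of RNA-World Replicators and Protocells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A configurable, seeded, agent-based Monte Carlo simulator of an
    RNA-world scenario on a toroidal lattice: non-enzymatic and
    ribozyme-catalyzed nucleotide chemistry, template-directed RNA replication
    with a tag-recognition polymerase ribozyme (REP), a nucleotide synthetase
    ribozyme (NSR), tag-flanked parasites, and membrane-bounded protocells
    that grow, divide, fuse, break, move, and engulf molecules from
    neighbouring lattice rooms. Provides the full parameter system with
    validated defaults, rocky/solution region profiles, scenario presets for
    ribozyme spread and naked-versus-protocell competition experiments, CSV
    time-series and snapshot recorders, and a command-line entry point. The
    simulation core is implemented in C++ for speed; every closed-form event
    probability is also exposed as a plain R function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    seqinr,
    jsonlite
Config/testthat/edition: 3
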
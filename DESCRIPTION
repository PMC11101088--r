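Package: aggsim
Title: Individual-Based Lattice Simulation of Aggregative Multicellularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit, stochastic, individual-based simulation of
    cooperator and cheater cells on a toroidal lattice with local resource
    dynamics, adhesion-based aggregation, size-dependent predation, and six
    population-level colonization mechanisms triggered by resource scarcity.
    Provides the asynchronous per-cell update engine (metabolism, resource
    uptake, division, association, dissociation, movement, predation),
    propagule formation and colonization of fresh habitats, replicate and
    parameter-sweep experiment drivers with outcome classification, trace and
    snapshot input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
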
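Package: mitoreticulum
Title: Spatially Resolved Fission-Fusion Dynamics of the Mitochondrial
    Reticulum on a Centrosomal Microtubule Cytoskeleton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the mitochondrial network (chondriome) of a spherically
    symmetric, centrosome-organized animal cell as a dynamic graph whose
    fission and fusion rates are shaped by the microtubule cytoskeleton.
    Microtubules are generated as freely rotating chains grafted at the
    centrosome; semi-analytic worm-like-chain theory supplies radial
    densities of fibers, fiber crossings and motor-protein-biased
    mitochondrial occupancy; the resulting position-dependent tip-to-tip
    and tip-to-side fusion/fission rates feed both a deterministic
    mass-action steady state of node densities and an exact event-driven
    (Gillespie) agent-based simulation with cluster-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
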
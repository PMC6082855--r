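Package: ccm
Title: Chromosome Copolymer Model Simulation and Chromatin Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates interphase chromosomes as a two-state (active/repressive)
    bead-spring copolymer with permanent loop bonds at CTCF anchor positions,
    and quantifies the resulting structure and dynamics. Includes Brownian and
    Langevin integrators with a compiled force kernel, contact-map statistics
    (contact probability curves, compartment co-clustering, directionality-index
    TAD calling, radial distributions), distance-space analyses (mean distance
    maps, Ward linkage matrices, contact-distance scaling, gyration-tensor
    shapes, droplet coarsening), and glassy-dynamics observables (mean square
    displacements and exponent distributions, intermediate scattering functions,
    fourth-order susceptibility, Van Hove functions). Synthetic annotation,
    loop-set and trajectory generators make the package self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
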
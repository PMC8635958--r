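Package: chemomech
Title: Mechanochemical Particle-Spring Model of Eukaryotic Chemotaxis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates single-cell eukaryotic chemotaxis with a
    two-dimensional particle-spring cell whose membrane carries a
    multilayered reaction-diffusion signalling network (receptor-level
    balanced inactivation, Rac/RhoA regulation with FilGAP-mediated
    antagonism, PIP3/PIP2 interconversion with stochastic PI3K/PTEN
    membrane translocation) coupled to a strain-gated FLNa-FilGAP
    mechanosensing pathway on the deforming lamellipodial network.
    Reproduces correlated random migration, chemotaxis toward shallow
    attractant gradients, FilGAP and PI3K mutant phenotypes, and
    navigation among circular obstacles.  Provides velocity,
    chemotaxis-index and coverage-ratio metrics plus kymograph export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    interp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
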
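Package: dpdmix
Title: Dissipative Particle Dynamics of Two-Component Lipid Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained dissipative particle dynamics (DPD) simulation and
    analysis of binary single-tail lipid mixtures in water. Provides the
    Groot-Warren DPD force field (soft conservative repulsion, pairwise
    dissipative/random thermostat, harmonic bonds and angles), a modified
    velocity-Verlet integrator with cell-list neighbour search under full
    periodic boundaries, seeded builders for layered-bilayer, random,
    perforated-membrane and vesicle starting configurations, and an analysis
    battery: density profiles, P2 orientational order, gyration-tensor shape
    statistics, leaflet mixing counts, bilayer thickness, pore detection,
    structure classification, three-stage dynamics segmentation, and the
    Irving-Kirkwood pressure tensor with slab-resolved interfacial tension.
    Includes a configuration-driven pipeline for phase-diagram sweeps over
    tail-chain lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
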
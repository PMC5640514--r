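Package: myospread
Title: Agent-Based Simulation of Myonuclear Positioning and Proximity-Labeling Quantitation in Myotubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of nuclear positioning in multinucleated
    muscle cells (myotubes), together with the downstream statistics used to
    score it and a proximity-labeling quantitation pipeline. The simulator
    integrates overdamped Langevin dynamics of nuclei, centrosome-like bodies
    and semiflexible microtubules confined in an elliptical cell, with
    microtubule dynamic instability (force- and tubulin-pool-dependent growth,
    growth-rate-dependent catastrophe, no rescue), nucleation from the nuclear
    envelope or from cytoplasmic bodies, and Hookean motor/crosslinker
    connectors (nuclear-envelope dynein and kinesin-1, cytoplasmic passive and
    motile crosslinkers) with first-order binding kinetics and linear
    force-velocity. Downstream tools compute the nuclear spreading factor
    along the myotube axis, compare condition ensembles by rank-sum tests,
    normalize BioID/TMT reporter tables to bait-derived correcting factors,
    and apply a replicate-consistent myotube-enrichment filter. Seeded
    synthetic-data generators provide ground-truth inputs for every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
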
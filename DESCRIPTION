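Package: ugimorph
Title: Morphological Pattern Analysis, CA-Markov Simulation and
    Connectivity of Urban Green Infrastructure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the spatio-temporal analysis and scenario prediction
    of urban green infrastructure (UGI) from categorical land-cover rasters.
    Segments a binary green-infrastructure foreground into the seven
    morphological spatial pattern analysis (MSPA) structural classes (core,
    islet, edge, perforation, bridge, loop, branch); computes land-cover
    change-rate indices, area-weighted barycenter migration tracks and
    Cohen's kappa map agreement; fits a Markov class-transition model
    coupled to a cellular-automata spatial allocator for multi-scenario
    land-cover prediction with policy constraints (frozen classes,
    protected masks, terrain suitability); and assesses core-to-core
    connectivity by least-cost corridors and circuit-theory current
    density (pinch points, effective resistance). A seeded synthetic
    landscape generator produces multi-date land-cover series, digital
    elevation models and policy masks so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
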
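Package: ras1zone
Title: Reaction-Diffusion Simulation of the Fission-Yeast Ras1 Mating Patch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the exploratory Ras1-GTP polarity patch of mating
    fission yeast as a reaction-diffusion system on a Voronoi-discretized
    spherocylindrical membrane. Provides a conservative discrete
    Laplace-Beltrami operator on the curved surface, FRAP (fluorescence
    recovery after photobleaching) simulation and grid-search fitting of
    membrane diffusion coefficients and cytoplasmic exchange rates, the
    GTPase patch model with GEF-mediated positive feedback (finite
    cytoplasmic pool, quasi-static or explicit GEF binding) and Gap1
    negative feedback, multiplicative activation noise, patch detection,
    period estimation, dynamical-regime classification for phase diagrams,
    quantification of patches in 1D cortical intensity profiles, and a
    reproducible scenario runner with parameter sweeps and synthetic-data
    fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
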
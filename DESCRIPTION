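Package: metafes
Title: Metadynamics Free-Energy Landscapes of Ligand Unbinding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for metadynamics-based analysis of ligand-unbinding
    free-energy landscapes: collective variables (center-of-mass distance
    and coordination number with a data-driven switching function), a
    Langevin sampler with standard and well-tempered Gaussian hill
    deposition on analytic toy potentials, free-energy-surface
    reconstruction from deposited hills on a rectangular grid with an
    unbinding stop criterion, basin assignment and minimum-energy-path
    profiles with activation energies, and per-state structural statistics
    on trajectories (hydrogen-bond occupancies, mass-weighted RMSF, gromos
    RMSD clustering, nick-width distances). Includes synthetic generators
    for toy energy landscapes and mock ternary-complex trajectories with
    prescribed statistical structure, so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
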
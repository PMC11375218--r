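Package: electrometry
Title: Effective Charge of Single-Stranded Nucleic Acids from Escape-Time
    Electrometry and Poisson-Boltzmann Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing escape-time electrometry experiments on
    charged biomolecules in nanofluidic slit traps, and for computing the
    corresponding theoretical effective charges from continuum
    electrostatics.  Includes nonlinear Poisson-Boltzmann solvers on
    graded finite-volume grids (planar slit, slit-with-pocket
    cross-section, axisymmetric finite rod, and 3D atomistic/bead charge
    distributions with an ion-accessible surface), electrostatic
    free-energy and ion-excess functionals, far-field and free-energy
    definitions of the renormalized effective charge, maximum-likelihood
    fitting of truncated-exponential residence-time distributions,
    Brownian-dynamics escape simulations, device calibration against
    reference molecules, rigid-rod inversion of measured effective charge
    into axial charge spacing, and synthetic-data generators (escape
    events, worm-like-chain conformational ensembles, bead structures)
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    generics,
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
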
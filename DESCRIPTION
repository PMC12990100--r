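Package: ionflux
Title: Finite-Field Ion Transport Analysis for Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ionic transport in finite-field molecular
    dynamics simulations of electrolytes. Computes field-induced forces from
    atomic polar tensors with acoustic sum-rule enforcement, solvation-shell
    structure (radial distribution functions, smooth coordination numbers,
    potentials of mean force, dipole tilt-angle densities), shell-exchange
    kinetics (continuous survival correlation and lifetimes, velocity
    autocorrelation, Green-Kubo diffusion with bootstrap and finite-size
    extrapolation, velocity density of states and cage-rattling periods),
    ionic conductivity from both the finite-field current-density route and
    the Nernst-Einstein route, and the decomposition of the ionic current into
    vehicular and structural contributions. Includes a finite-field Langevin
    dynamics simulator of a single cation in a bath of dipolar solvent
    particles for method validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
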
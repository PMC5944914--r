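Package: antcargo
Title: Bistable Dynamics of Cooperative Cargo Transport by Ants Near Obstacles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the collective transport of a cargo by a group of ants
    whose path is blocked by a linear obstacle with a narrow opening.
    Provides the deterministic mean-field oscillator for the cargo
    (a puller/lifter tug-of-war driven by force-dependent role switching,
    with informed ants acting as a restoring force toward the opening),
    its full bifurcation structure (subcritical Hopf, homoclinic and
    saddle-node of cycles, with phase diagrams over the restoring-force /
    individuality plane), exact Gillespie stochastic simulators for three
    1D kinetic schemes and for a 2D ring cargo carried along a wall, and
    trajectory analysis utilities that segment motion into convergent and
    oscillatory modes and quantify turning and dwell statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
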
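Package: kneerig
Title: Patellofemoral Contact Simulation on a Sensorized Knee Test Rig
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multibody simulation of patellar tracking and patellofemoral
    contact on a spring-actuated knee test rig after total knee replacement.
    Implements an augmented-Lagrangian index-3 formulation in mixed (natural
    plus relative) coordinates with Newmark integration and velocity and
    acceleration projections, analytic sphere-versus-polynomial-surface
    collision detection with the Flores continuous normal contact force
    model, marker-based reconstruction of guided joint angles, static
    equilibrium initialization, spring calibration with genetic-algorithm
    refinement, and Bland-Altman agreement reporting. A synthetic rig module
    generates complete marker and force captures with ground truth so that
    every stage of the pipeline can be exercised without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
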
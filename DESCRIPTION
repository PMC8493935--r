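Package: routenav
Title: Behavioral Dynamics of Route Navigation and Obstacle Avoidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for goal-directed steering through
    obstacle fields with a dynamical perceptual-motor primitive model of
    heading dynamics (damped goal attraction plus exponentially decaying
    obstacle repulsion). Provides the task environment of a 40 x 40 m
    navigation game with capped turning kinematics, raycast observations and
    discrete actions; trajectory preprocessing (resampling, admissibility
    filters, binning onto a fixed y-grid); trajectory-population comparison
    statistics (pairwise binned distances, percentile confidence bands,
    route-signature counting); model fitting by differential evolution
    minimizing a dynamic-time-warping cost, with per-agent characteristic
    parameters and parameter-recovery validation; and a synthetic-data
    generator producing human-like and agent-like trajectory populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    MASS,
    e1071,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
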
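Package: cnmr
Title: Cluster-Based Network Modeling of Nonlinear Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven reduced-order modeling of complex nonlinear dynamical
    systems from time-resolved snapshot data. Snapshots are coarse-grained into
    centroids with k-means++ clustering, the dynamics are encoded as a directed
    network whose transitions follow an order-L Markov chain on the visited
    centroids with data-inferred transition times, and new trajectories are
    synthesized as constant-velocity flights between centroids. Includes
    snapshot proper orthogonal decomposition for high-dimensional states,
    validation via autocorrelation functions and cluster-population statistics,
    rare-event (burst) probability forecasting, and interpolation of the model
    to unseen control-parameter settings. Benchmark generators (Lorenz,
    Roessler, pulse-train and intermittent-burst surrogates) make the whole
    workflow reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
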
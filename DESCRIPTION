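Package: eodkin
Title: Quantitative Motor-Pattern Analysis for EOD-Triggered Fish Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative analysis of tracking data from pulse-type
    weakly electric fish, where each video frame is triggered by an electric organ
    discharge (EOD). Converts head trajectories into egocentric thrust, slip and
    yaw velocities; clusters them into prototypical movements (PMs) with a
    replicate-stability and silhouette-quality scan over the cluster count;
    extracts homogeneous PM chains and classifies stationary versus backwards
    swimming behavior; mines high-probability PM transition sequences
    (super-prototypical movements, SPMs) from a Markov transition model with
    mirror-pair and composition merging; applies spatial conditionals for object
    approach and departure; and analyses EOD sampling statistics (instantaneous
    frequency, per-night z-scoring, occupancy and frequency maps, distance
    profiles). A synthetic session generator with ground-truth labels makes every
    stage testable without video data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    cluster,
    mclust,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
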
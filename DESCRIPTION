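Package: munet
Title: Sensor-Space Functional Networks of the Developing Mu Rhythm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of band-limited sensor-space
    functional connectivity in the sensorimotor cortex.  Computes
    synchronization likelihood (SL) between multichannel recordings
    within an individual mu-rhythm frequency band, thresholds average
    SL matrices at Median + 1 MAD, screens subjects for inter-sensor
    distance bias and degree comparability, derives weighted
    segregation (clustering coefficient, local efficiency) and
    integration (characteristic path length, global efficiency)
    measures, and runs mixed-design group statistics.  Includes a
    synthetic multichannel MEG-like cohort generator with controllable
    pairwise coupling and event-locked mu suppression so the full
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
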
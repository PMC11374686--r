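Package: batmap
Title: Spatial and Social Coding Analyses for Bat Hippocampal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dorsal-CA1 recordings from freely flying
    bats in the presence of human experimenters. Segments 3D tracking into
    flight, rest and human-traverse epochs; clusters stereotyped flight
    trajectories; builds occupancy-normalized 2D and linearized 1D firing
    rate maps; computes Skaggs spatial information with circular-shift
    shuffle nulls across self, conspecific and human reference frames; runs
    label-permutation tests for experimenter-identity and conspecific-presence
    modulation of peri-event firing; classifies conjunctive coding of human
    identity and landing location with nested linear-model comparisons; and
    quantifies rate versus global remapping with matched null constructions.
    Includes an inhomogeneous-Poisson synthetic-session generator with ground
    truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
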
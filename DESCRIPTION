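Package: wtrackseq
Title: Multi-Timescale Ensemble-Sequence Analysis of W-Track CA1-PFC Recordings
Version: 0.1.0
Authors@R:
    person("Maze", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous dorsal CA1 and prefrontal
    cortex (PFC) ensemble recordings from the W-track continuous spatial
    alternation task. Provides behavioral linearization and trial
    segmentation, linearized place-field rate maps with trajectory
    selectivity and field asymmetry, theta phase extraction and
    population-defined theta-cycle segmentation, sharp-wave-ripple (SWR)
    detection, memoryless Poisson Bayesian decoding of position and choice,
    theta-sequence detection (weighted correlation and best-fit-line
    goodness-of-fit with circular shuffles), theta cycle-skipping index
    from duration-corrected autocorrelograms, circular-linear phase
    precession regression, replay detection inside SWRs, CA1-PFC
    reactivation strength, and trial-by-trial classifiers predicting
    choice and outcome. A fully synthetic session generator with known
    ground truth makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
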
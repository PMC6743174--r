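Package: qmnase
Title: Quantitative MNase-Seq Analysis of Nucleosome Occupancy and Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic analysis of micrococcal nuclease (MNase) digestion time
    courses. Models nucleosome release from chromatin and over-digestion decay
    as a consecutive first-order reaction chain, and fits per-locus nucleosome
    occupancy together with release and decay rate constants from spike-in
    calibrated fragment counts. Includes paired-end fragment filtering and
    spike-in normalization, dyad and coverage track construction, nucleosome
    position calling by cluster medians, fragment-length by A/T-content
    two-dimensional occupancy summaries, a digestion time-course simulator
    with known ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
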
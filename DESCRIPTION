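Package: kymoflux
Title: Kymograph-Based Vesicle Transport and Calcium Trace Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of axonal transport and neuronal calcium
    activity from time-lapse fluorescence microscopy. Builds calibrated
    position-by-time kymographs from image streams along a neurite path,
    detects and classifies directed vesicle transport events, computes
    GCaMP trace metrics (dF/F relative to a minimum baseline, peak
    amplitudes, total supra-baseline activity), and provides the
    accompanying statistical layer: iterative modified Thompson-Tau
    outlier screening followed by two-tailed two-sample t-tests, including
    tests from printed summary statistics. A synthetic-data module
    simulates photobleached neurite image streams with moving diffraction
    limited vesicles and somatic calcium traces with known ground truth,
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
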
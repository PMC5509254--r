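Package: ligomir
Title: Absolute miRNA Quantification from Length-Coded Ligation Gel Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multiplexed, length-coded
    ligation miRNA assays read out by denaturing PAGE. Simulates the assay's
    fluorescent band readout (capture and coding ligation efficiencies,
    per-miRNA response factors, multiplicative intraday noise, per-gel scanner
    drift, background-RNA ligation inhibition, optional cross-talk and
    saturation), renders and quantifies gel images (lane segmentation,
    rolling-minimum background subtraction, prominence-based band detection,
    ladder calibration, length-based band assignment), calibrates intensities
    to absolute copies per cell via spike-in drift correction and per-miRNA
    log-log standard curves, and provides the assay's statistical toolkit:
    normalization schemes, fractional-expression differential metrics,
    titration-order validation, cross-talk matrices, fold-change
    resolvability t-tests, CV summaries, and Monte-Carlo copy-number error
    budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
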
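Package: MitoPulse
Title: ATP Pulse Detection and Mitochondrial Cluster Quantification in
    Maturing Oocytes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing firefly-luciferase luminescence recordings
    and mitotracker-stained equatorial-section images from maturing mouse
    oocytes. Fits a scaled Weibull or log-normal expression/decay baseline
    to photon-count traces, detects supra-baseline ATP pulses from
    Poisson-scaled residuals, quantifies mitochondrial clusters by
    thresholding and connected-component labelling with a physical-unit
    particle floor, scores peri-nuclear mitochondrial rings, and summarises
    treatment cohorts with unpaired t-tests and binomial incidence
    fractions. Ships synthetic-data generators with ground truth for both
    traces and images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    igraph,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
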
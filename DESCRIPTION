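Package: receptomics
Title: Receptor-Array Biosensor Simulation and Analysis for a Microfluidic Taste Chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for flow-cell receptor-array
    (FRET calcium reporter) experiments on taste GPCRs. Models loop-injection
    exposure profiles with a tanks-in-series residence-time cascade, generates
    synthetic two-channel fluorescence traces for spotted arrays of sweet and
    bitter taste receptors, and computes the downstream metrics: iRatio peak
    responses, fluorescein-referenced onset and delta-fwhm lingering, Hill
    EC50/EC10 dose-response estimates, and mixed-model multiplicative
    treatment contrasts including antagonist blocking percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
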
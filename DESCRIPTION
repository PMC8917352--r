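Package: frapkit
Title: FRAP Recovery Analysis and Chromosome-Scale Enrichment Statistics
Version: 1.0.0
Authors@R:
    person("Imaging Methods", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantitative analysis of fluorescence recovery
    after photobleaching (FRAP) time-lapse movies: sub-pixel drift
    correction by upsampled cross-correlation, automated bleach-spot
    detection from the pre/post difference image (Otsu thresholding),
    acquisition-photobleaching correction, double normalization of
    recovery curves, monoexponential recovery fitting with mobile-fraction
    and half-time estimation, and cohort-level statistics. Includes a
    synthetic-movie generator with known ground truth for validation, and
    chromosome-scale enrichment statistics for dosage-compensation
    studies: autosome-standardized ChIP signal spreading windows and
    unity-normalized Hi-C contact-decay curves with X-to-autosome ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
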
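Package: methylQC450
Title: Compact Quality-Control Summaries for Illumina 450k Methylation Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality control of Infinium 450k-style DNA methylation arrays from
    methylated/unmethylated signal matrices. Builds compact, probe-type-stratified
    quantile summaries of raw and normalized data (Beta, M-value, copy number and
    channel intensities), flags low-quality samples from median channel
    intensities, predicts sample sex from X/Y copy-number medians, runs PCA on
    the most variable autosomal Beta values for batch-effect and
    design-confounding exploration, and renders a static HTML quality-control
    report. A seeded synthetic-data generator produces 450k-like datasets with
    controllable sex, batch and sample-quality effects for testing and
    demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
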
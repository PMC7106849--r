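Package: isopanel
Title: Isoform Quantification from Probe Panels and Cross-Platform
    Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies transcript-isoform expression from targeted
    hybridization probe panels (NanoString nCounter style) by non-negative
    least-squares deconvolution of probe intensities over a probe-isoform
    indicator matrix, with housekeeping geometric-mean normalization,
    identifiability diagnostics for probe designs, within-gene isoform
    proportions and a proportion-difference statistic for comparing
    platforms, a cross-platform concordance battery (per-sample and pooled
    Spearman correlation, low-expression subsets, tissue fold changes,
    one-way ANOVA differential expression), comparative-Ct conversion of
    RT-qPCR data to isoform proportions, and a multi-platform expression
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
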
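Package: markermatch
Title: Proximity-Based Probe Matching Across Genotyping Arrays for Joint
    CNV Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes probe content across genotyping-array manifests with
    a two-stage greedy matching algorithm (exact positional intersection
    followed by nearest-neighbour matching within a maximum genomic
    distance), so that copy-number variant (CNV) calling can use a shared,
    dense probe set instead of the sparse consensus intersection. Also
    provides a CNV callset validation framework around PennCNV-style
    rawcnv files: partial confusion matrices, precision/recall-type
    metrics (sensitivity, FNR, PPV, FDR, F1, Fowlkes-Mallows, Jaccard),
    size/type/region-stratified evaluation, sample-wise false-positive
    attribution, and smoothed parameter-selection curves over a grid of
    maximum matching distances. Includes seeded simulators for paired
    manifests and paired truth/test callsets so the whole pipeline is
    testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
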
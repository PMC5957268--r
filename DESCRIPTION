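Package: epibase
Title: Baseline Liver Epigenome Profiling on Binned Coverage Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building baseline DNA-modification (5mC/5hmC) and
    enhancer chromatin-mark (H3K4me1/H3K27ac) landscapes from mapped-read
    interval files: fixed 150 bp binned coverage with library-size
    normalization and input subtraction, percentile-threshold peak calling,
    genomic-compartment annotation, length-normalized metagene profiling,
    promoter and gene-body differential-modification classification,
    poised/active enhancer definition, sample correlation and Ward
    clustering, and integration with expression matrices (quintiles,
    tissue-specific and housekeeping sets, gender-biased genes).  Includes a
    seeded synthetic-data generator that plants promoter, gene-body,
    enhancer and expression features with truth tables so the whole
    pipeline can be exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
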
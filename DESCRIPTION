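Package: tilemeth
Title: Comparative meDIP Tiling-Array Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative methylated-DNA
    immunoprecipitation (meDIP) tiling-array analysis of two inbred
    genotypes. Provides probe-level contrast modeling with
    empirical-Bayes moderated statistics, circular binary segmentation
    with Gaussian-mixture EM posterior classification of copy-number and
    differentially methylated segments, chromosome and metagene
    methylation profiling, an identical-by-descent pure-epiallele
    screen, and qPCR/near-isogenic-line based validation with cis
    versus trans inheritance classification. Includes a synthetic-data
    generator that emulates the statistical structure of two-color
    tiling arrays with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
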
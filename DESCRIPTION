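Package: chromcast
Title: Predict Genome-Wide Chromatin Accessibility from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains multi-level regression models that predict DNase I
    hypersensitivity at 200-bp genomic loci from gene expression profiles, and
    applies them to bulk, small-cell-number and pooled single-cell RNA-seq.
    Includes quantile normalization to a training reference, locus-level and
    cluster-level model averaging, permutation-control and mean-profile
    baselines, leave-one-cell-type-out cross-validation with cross-locus and
    cross-sample correlation statistics, transcription factor binding site
    prediction by ranking motif sites on predicted accessibility, hybrid
    integration with measured ATAC-seq, differential-accessibility
    benchmarking, a training-test distance diagnostic, and a synthetic paired
    expression/accessibility data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
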
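Package: pritss
Title: Promoter-Context Scoring and Transcription Start Site Prediction for
    Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Octamer-based evaluation of plant promoter context and prediction
    of transcription start sites (TSS). Builds Intergenic Index (IGI),
    Promoter Index (PRI) and 5'UTR Index (FUI) score tables from TSS-anchored
    promoter sets, scans genomes into strand-specific smoothed score tracks,
    calls PRI peaks, predicts gene-model-associated and genome-wide 200-bp
    TSS windows with optional direction calling and FUI filtering, and
    evaluates predictions by sensitivity, precision and their harmonic mean
    with stratified breakdowns. Includes a synthetic-genome generator with
    planted promoter context for end-to-end benchmarking, readers and writers
    for FASTA, GFF3, bedGraph, BED6 and score-table TSV, and ggplot2 plotting
    methods.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
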
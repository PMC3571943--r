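Package: readqc
Title: Quality Assessment and Filtration for Illumina FASTQ Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streaming quality-control toolkit for Illumina sequencing
    reads. Computes per-cycle Phred-score statistics, base composition,
    read-length and read-quality distributions, per-tile quality summaries
    and paired-end quality correlation from FASTQ files (plain or gzip,
    phred+33 or phred+64), writes them as tab-delimited report tables, and
    renders the corresponding charts. Provides four composable filtration
    stages (end trimming, quality, length and tile filters) with correct
    paired-end singleton routing, a command-line interface, and a seeded
    synthetic-read generator for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    optparse,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
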
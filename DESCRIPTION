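Package: mitoblocks
Title: Copy-Number Heteroplasmy, Tandem Repeats and Rearrangements in
    Mitogenomes from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects structural heteroplasmy in circular mitochondrial
    genomes from noisy long reads. Matches k-mers of a query gene against
    raw reads, clusters matches into blocks under a maximum-gap rule, and
    counts gene copies per read to build a copy-number spectrum across
    reads spanning a pair of flanking anchor genes. Screens mitochondrial
    reads from whole-genome pools by matching-block length (rejecting
    nuclear copies of mitochondrial DNA), characterises control-region
    tandem repeats (period, fractional copy number, consensus), and
    decomposes assemblies into ordered, stranded gene blocks to classify
    tandem duplications, remnant duplicate units and inversions. Includes
    a simulator for heteroplasmic read pools with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
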
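Package: dopseqr
Title: Chromosome Content Detection from Isolated-Chromosome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects reference-genome regions present on isolated (flow-sorted or
    microdissected) chromosomes from the spacing of mapped read positions, estimates
    per-B-chromosome copy number from windowed whole-genome read depth, measures
    breakpoint concordance between the two methods, and compares region and gene
    content across samples and species. Ships a synthetic-data generator with known
    ground truth (planted regions, deletions, amplifications) so the whole pipeline
    is testable without sequencing data, plus the published red fox and Chinese
    raccoon dog B-chromosome region tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    yaml
Suggests:
    BiocGenerics,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
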
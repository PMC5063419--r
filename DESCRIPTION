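Package: adapterscout
Title: De Novo 3' Adapter Prediction for Small RNA Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the 3' adapter sequence of single-end small RNA
    sequencing libraries directly from the reads, without prior knowledge of
    the library preparation protocol. Counts k-mers over a sample of reads,
    removes low-complexity and infrequent k-mers, assembles the survivors by
    suffix-prefix overlap, and reports scored adapter candidates; an
    iterative mode tallies normalized scores across several (k, R) parameter
    settings, and an exhaustive mode selects the adapter that maximizes the
    genome-mapping rate of the clipped reads under a user-defined mapping
    command, flags poor-quality libraries, and detects libraries whose
    adapters were already removed. Includes Mott quality trimming, adapter
    clipping with cleansed FASTQ output, a seeded synthetic-library
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    vctrs,
    withr
Suggests:
    S4Vectors,
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
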
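Package: mitocomp
Title: Comparative Analysis of Annotated Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes: feature-map accounting (gene sizes, intergenic
    spacers, overlaps, the light-strand replication origin, strand census),
    nucleotide composition and AT/GC skew, codon usage and relative
    synonymous codon usage (RSCU) under the vertebrate mitochondrial code,
    codon-position-partitioned p-distance, and Nei-Gojobori (1986) Ka/Ks
    with Jukes-Cantor correction. Includes transcribed feature tables for
    three Gerres mitogenomes and a seeded synthetic-mitogenome generator
    so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
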
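Package: ssrmine
Title: Batch Mining and Comparison of Perfect and Imperfect Microsatellites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects perfect, imperfect and compound microsatellites (simple
    sequence repeats, motif size 1-6 bp) in one or many FASTA genomes,
    classifies tracts into coding and non-coding regions from GenBank-derived
    protein tables (PTT), and aggregates the results into cross-genome
    comparison tables, motif-frequency matrices, top-motif rankings and
    chart-ready datasets. Includes a deterministic synthetic-genome generator
    with planted repeat truth sets for validation, and a project runner that
    writes a complete per-genome and project-level report folder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    jsonlite,
    rlang,
    generics,
    ggplot2,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
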
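Package: pinmapr
Title: Pin- and Brace-Anchored Short-Read Mapping with a Compact Hash Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A short-read mapper built around a k-mer hash index whose rows
    flag words occurring exactly once in the reference (pins). Paired reads
    are placed by searching for a brace, a pair of pins with compatible
    reference coordinates, falling back to seed-and-extend over low- then
    high-abundance seeds with x-drop gapless extension and banded gapped
    alignment. Includes MAPQ estimation, a locus-anchored read-simulation
    benchmark with quality-driven substitution errors and per-read/per-locus
    accuracy metrics, a genome mappability scanner, and deterministic
    synthetic-genome fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
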
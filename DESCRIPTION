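Package: mosaicscan
Title: Detection of Recent Genomic Exchanges and Recombination Traces in Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics pipeline for phage and prophage genome
    mosaicism. Detects recently exchanged segments (mosaics) between pairs of
    genomes with a seed-and-extend local aligner, screens genome pairs by
    fragment-based average nucleotide identity (ANI) with relaxed scoring,
    filters insertion-sequence derived hits, realigns 2-kb mosaic flanks by
    affine-gap dynamic programming and calls traces of homologous
    recombination as 50-bp alignment windows elevated at least 10 identity
    points above the background, with an analytic and a permutation null
    model for chance traces. Includes perfect-identity segment and MEPS
    statistics, per-lifestyle-category summaries, and a seeded synthetic
    phage-genome cohort generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
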
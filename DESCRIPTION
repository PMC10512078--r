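Package: fusionneo
Title: Chimeric RNA Fusion Detection and Neoantigen Peptide Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering tumor-specific neoantigen
    candidates from chimeric (fusion) RNAs in paired-end RNA-seq. Detects
    fusion junctions from split (junction-crossing) reads and discordant read
    pairs under an explicit alignment cost model with cohort-level
    false-positive and false-negative filters, assembles consensus fusion
    junctions and fusion cDNA models, enumerates junction-overlapping k-mer
    neopeptides from truncation open reading frames, ranks peptides by MHC
    class I binding promiscuity from an external IC50 table, and scores
    ELISpot T-cell response assays. Includes a synthetic-cohort read
    simulator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
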
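Package: avigc
Title: Life History, Recombination and Base Composition Evolution in Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying GC-biased gene conversion (gBGC) as a driver
    of between-lineage differences in avian base composition. Computes GC
    content by codon position and for introns from ortholog alignments,
    estimates species-tree branch lengths in coalescent units from gene-tree
    discordance and reconstructs ancestral effective population sizes, fits a
    Tamura (1992) substitution model and maps weak-to-strong and
    strong-to-weak substitutions onto branches to obtain equilibrium GC3*,
    computes a time-corrected GC3 conservation index, joins ortholog
    composition statistics to recombination-map windows and chromosome
    classes, and models the approach of GC content to its gBGC equilibrium.
    Includes a synthetic-data generator with the statistical structure the
    analysis assumes, so every stage is testable without external genome
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
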
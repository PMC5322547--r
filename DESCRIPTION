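Package: homeokit
Title: Homeobox Repertoire Annotation and Developmental Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect homeodomains in predicted proteomes with a
    dual profile/similarity search, classify hits into the eleven metazoan
    homeobox classes and their gene families using diagnostic residues,
    insertions and companion-domain motifs, group divergent genes into
    lineage-specific clades with neighbor-joining trees and bootstrap
    support, date clade origins from taxonomic distributions, detect
    physical clustering of homeobox genes on genome scaffolds, and test
    whether evolutionarily novel genes peak early or late in a
    developmental expression series (the hourglass or egg-timer pattern).
    Includes seeded simulators for proteomes, scaffold maps and stage
    series with known ground truth, and machine-readable transcriptions
    of the Pacific oyster homeobox repertoire tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    jsonlite,
    phangorn,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
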
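Package: pangemr
Title: Pan-Genome Guided Metabolic Network Reconstruction and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pan-genomic ortholog presence/absence matrices from protein
    sequences, estimates core- and pan-genome sizes by random genome-order
    sampling with Heaps-law and exponential-decay fits, pivots the ortholog
    matrix into a functional matrix via EC numbers and enzyme-name synonym
    dictionaries, consolidates per-species genome-scale metabolic models into a
    genus-level pan-GEM, gap-fills draft models against a universal reaction
    database simultaneously across many growth conditions with a mixed-integer
    linear program, predicts minimal media, and compares species by Jaccard
    clustergrams of pathway reaction presence. A synthetic-data generator with
    planted ground truth (ortholog families, network gaps, phenotype-array
    growth calls, annotation synonym splits) makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    xml2
LinkingTo: Rcpp
Suggests:
    boot,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
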
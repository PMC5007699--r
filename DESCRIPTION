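Package: lecfam
Title: Genome-Wide Cataloguing of Lectin Receptor-Like Kinase Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterise plant lectin receptor-like
    kinase (LecRLK) gene families from a proteome: reciprocal
    similarity-threshold homolog expansion with affine-gap Smith-Waterman
    alignment, dual-domain (lectin plus kinase) family filtering with
    G/L/C lectin typing, an eight-class transmembrane-orientation
    classifier driven by topology tables or a built-in hydropathy
    predictor, tandem-duplication cluster detection on genome annotation,
    neighbor-joining phylogenetics with protein Jukes-Cantor distances and
    column-bootstrap supports, and FPKM zone-based tissue-specificity
    analysis. A synthetic-catalogue simulator with complete ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
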
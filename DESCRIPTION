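Package: rgascape
Title: Genome-Wide Characterisation of Plant Resistance Gene Analogues
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising resistance gene analogues (RGAs) in
    plant genomes. Classifies genes into RLK, RLP, NLR, TM-CC and RPW8
    classes from domain-architecture calls, computes chromosome-level
    landscape statistics (densities, shares, size-versus-count
    comparisons, positional end-bias profiles), detects physical gene
    clusters within a genomic distance threshold, clusters protein
    sequences by pairwise similarity, identifies homologues of cloned
    disease-resistance genes with E-value/similarity/length filtering,
    co-localises receptor genes with disease-resistance QTL intervals,
    and builds UPGMA trees from Jukes-Cantor-corrected protein distances
    with column-resampling bootstrap support. A synthetic-genome
    generator with known ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
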
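Package: slscreen
Title: Pooled shRNA Synthetic-Lethality Screen Simulation and Hit Calling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled shRNA dropout screens run in a
    two-genotype, two-replicate design, as used to find genes whose loss is
    synthetically lethal with a deficiency such as FANCA loss. Provides
    library annotation I/O, barcode counting from FASTQ with Hamming-distance
    matching, cross-replicate copy-number ratios with a five-fold dropout
    rule, gene-level candidate aggregation, per-hairpin z-scores,
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    correction and enrichment-map export, plus a fully seeded synthetic
    screen generator with ground-truth labels so every stage can be
    benchmarked without deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
biocViews: FunctionalGenomics, PooledScreens, GeneSetEnrichment, Software
RoxygenNote: 7.3.3
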
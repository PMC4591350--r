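Package: panpheno
Title: Comparative Genome Alignment Post-Processing and Phenotype
    Microarray Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two computational tracks of a comparative
    bacterial genomics and phenomics study. The genomics track turns
    pairwise local whole-genome alignments into similarity scores,
    unique genomic regions, order-conservation counts, a pan-genome
    Venn partition of CDS clusters and a pathway-completeness
    statistic. The phenomics track analyses OmniLog-style Phenotype
    Microarray kinetic curves: nine characteristic curve parameters,
    logistic/Gompertz/Richards sigmoid fits, activity areas,
    per-plate activity categories, and a sigma-threshold activity
    difference statistic that calls strain-specific substrates. A
    synthetic-data module generates genomes, annotations and PM
    plates with known ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    data.table,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
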
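Package: combind
Title: Combinatorial Transcription Factor Co-Occupancy Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of combinatorial binding by multiple
    transcription factors from ChIP-seq peak calls: union-region
    construction and exact occupancy-pattern enumeration over K factors,
    enrichment Z-scores under an independence null with a Monte-Carlo
    oracle, peak-to-gene annotation (promoter/intragenic/intergenic with a
    distance cap), promoter chromatin-state classification from histone
    marks, running-sum gene-set enrichment of pattern target lists against
    cell-type expression, consensus-motif scanning and enrichment in
    pattern-defined sequence subsets, and export of the core-circuit to
    effector-gene network. A fully seeded synthetic-data module generates
    peak landscapes, gene models, histone marks, expression matrices and
    sequences with ground-truth labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
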
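Package: TADconcord
Title: Concordance and Feature-Enrichment Metrics for Topologically
    Associating Domain Partitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Metrics and procedures for evaluating partitions of a
    chromosome into topologically associating domains (TADs). Implements
    the Measure of Concordance between two partitions with inter-TAD gaps
    treated as clusters, boundary and TAD conservation at a bin-level
    tolerance radius, cross-resolution boundary containment, consolidation
    of boundaries shared across callers, Hi-C contact-matrix preprocessing
    (map-resolution selection by the 80%/1000-contacts rule, binomial read
    subsampling, iterative correction, and Poisson regression on local
    genomic features), structural-protein peak profiles and fold changes at
    boundaries, histone-mark log-ratio significance within domains with a
    permutation null and Benjamini-Hochberg FDR, extraction of nesting
    levels from hierarchical domain sets, and seeded generators of
    synthetic contact matrices, peak sets, and signal tracks with planted
    domain structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
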
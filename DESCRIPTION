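Package: poolscape
Title: Pool-Seq Population Genomics and Climate Genomic Offset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled whole-genome resequencing (pool-seq) data for
    landscape and seascape genomics. Reads PoPoolation2-style synchronized
    allele-count files, estimates pool-aware allele frequencies with coverage
    and minor-allele-frequency filters, computes per-SNP and windowed F_ST,
    an ANOVA pairwise F_ST estimator correcting for both pool-size and
    read-depth sampling, windowed nucleotide diversity and Tajima's D,
    isolation-by-distance Mantel tests with great-circle and least-cost ocean
    distances, principal component and covariance-tree summaries of population
    structure, redundancy-analysis genotype-environment association with
    permutation tests, Mahalanobis outlier detection with FDR control, and
    adaptive-index / genomic-offset rasters under projected climate scenarios.
    Includes a fully seeded synthetic pool-seq generator (Balding-Nichols
    population frequencies, binomial pool and read sampling, gridded
    environmental layers) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    geosphere,
    igraph
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
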
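Package: divomics
Title: Multi-Omic Divergence Analysis for Two Selected Lines
Version: 0.9.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of genetic and epigenetic divergence between
    two populations under divergent selection, from genotypes and read
    intervals to integrated calls. Implements genotype quality filters and
    allele-based chi-squared association with permutation and
    Benjamini-Hochberg FDR, Weir-Cockerham Fst with windowed Tajima's D and a
    ten-category selection-signature classification, detection of fixed allele
    differences and of CpG-dinucleotide loss and gain against a reference
    genome with 1/16-expectancy enrichment statistics, window-based
    copy-number calling from two pooled libraries (Gaussian ratio
    approximation of Poisson counts, including the best-window recommendation
    formula), MeDIP-seq windowed differential-methylation calling with
    stacked-read filtering and CpG-coupling normalization, genomic feature
    annotation with deterministic precedence, and cross-omic interval overlap
    integration with hypergeometric testing. A synthetic-data module generates
    a complete two-line dataset (genome, genes, genotypes, MeDIP reads, pooled
    depths, repeats, QTLs) with a machine-readable truth manifest so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
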
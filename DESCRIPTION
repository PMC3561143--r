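Package: pedSGS
Title: Weighted Pairwise Shared Genomic Segment Analysis in Extended
    Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Localization of disease susceptibility loci in extended
    high-risk pedigrees from dense SNP genotypes using shared genomic
    segment statistics.  Implements per-locus identity-by-state sharing
    counts, run lengths, the all-case SGS statistic and the
    meiosis-weighted pairwise pSGS statistic, a gene-dropping Monte
    Carlo null built on a Markov haplotype model of linkage
    disequilibrium and genetic-map recombination, empirical per-locus
    p-values, nominal region calling, per-genome false-positive (mu)
    rates and empirical genomewide suggestive/significant thresholds,
    cross-pedigree sharing analysis, SNP quality control for PLINK
    text PED/MAP data, and a fully seeded synthetic-data generator
    with an embedded shared risk haplotype for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
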
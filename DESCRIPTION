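Package: sparsemeth
Title: Analysis of Sparse Insect CpG Methylomes from Bisulfite Sequencing Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of whole-genome bisulfite sequencing for
    sparsely methylated genomes such as those of Lepidoptera. Calls
    per-CpG methylation status with a binomial test against the bisulfite
    non-conversion rate under Benjamini-Hochberg false discovery control,
    summarises methylation ratios (mCpG/CpG) over exons, introns and 2 kb
    upstream regions, computes CpG observed/expected depletion per gene,
    tests modality of methylation-level distributions with Hartigan's dip
    statistic, relates gene-body methylation to expression, performs
    Fisher-exact term enrichment, and compares targeted bisulfite amplicon
    panels between two phenotype groups. A synthetic-data generator
    produces genomes, annotations, cytosine count tables, expression
    tables and amplicon panels with the statistical structure the analysis
    assumes, so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    BiocGenerics,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
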
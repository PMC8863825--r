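Package: mirflow
Title: Circulating Small-RNA Quantification and Group-Wise Differential
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for circulating microRNA
    (miRNA) profiling by small RNA sequencing: adapter trimming, read
    collapsing, precursor-space mapping with fractional (1/N) counting of
    multi-mapping reads and 5p/3p arm assignment by the precursor-half
    rule; expression filtering and trimmed-mean-of-M-values (TMM)
    normalization; pairwise negative-binomial exact tests with common
    dispersion estimated by quantile-adjusted conditional maximum
    likelihood and Benjamini-Hochberg false-discovery-rate control;
    Spearman correlation of miRNA expression with physiological
    parameters; and principal component analysis of the combined
    miRNA-phenotype matrix. Includes a synthetic-data module generating
    precursor references, negative-binomial counts with known
    differential-expression ground truth, phenotype tables and FASTQ
    reads, so that every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    limma,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
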
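Package: sweepscan
Title: Selection-Signature Scans in Divergently Selected Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide detection of recent selection in divergently
    selected populations from SNP-array genotypes. Provides quality
    control including an iterative r-squared-decay detector of misplaced
    SNPs, identity-by-state distances with classical multidimensional
    scaling, per-SNP Weir-Cockerham FST with sliding-window averaging and
    a joint top-quantile / heterozygosity-bin outlier criterion, and
    haplotype-based iHS and XP-EHH scans with window flagging and
    cross-test consensus regions. A forward-in-time Wright-Fisher
    simulator of a control line and directionally selected lines with
    known trait loci supplies fully specified test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
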
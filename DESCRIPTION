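Package: meripdm
Title: Differential RNA Methylation Analysis for MeRIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differentially methylated loci from MeRIP-seq (m6A-seq)
    experiments with paired INPUT and IP libraries. Concatenated-exon
    transcripts are divided into fixed-width bins and quantified from BAM
    alignments; INPUT libraries are normalized by median-of-ratios on
    gene-level counts and IP libraries by top-bin fold enrichment; IP counts
    are adjusted for pre-IP gene expression and each bin is tested with a
    Poisson-log-gamma random-effect regression (marginally negative
    binomial) supporting covariates, with Wald tests and Benjamini-Hochberg
    adjustment. Significant bins are merged into peaks and reported in
    BED12. Simulation generators and a sensitivity/FDR benchmark harness are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    optparse
Config/testthat/edition: 3
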
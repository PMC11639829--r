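Package: pigdeconv
Title: Breed Composition Deconvolution for Pigs from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a curated ancestry reference panel from labelled SNP
    genotypes and deconvolutes the ancestry (European versus Asian domestic)
    and breed (Duroc, Landrace, Yorkshire, indigenous, unknown) composition
    of purebred and crossbred pigs. Includes PLINK 1 and VCF genotype input,
    windowed linkage-disequilibrium pruning, a maximum-likelihood admixture
    estimator fitted by expectation-maximisation, PCA- and structure-based
    reference panel curation, identity-by-state distances with
    neighbour-joining trees, and a Balding-Nichols genotype simulator with
    crossbreeding schemes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
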
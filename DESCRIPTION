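Package: haploblup
Title: Haplotype-Block GBLUP for Genomic Prediction from Phased Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines haplotype blocks from phased SNP genotypes by fixed SNP
    count, fixed physical length, or adjacency-constrained hierarchical
    clustering on D-prime linkage disequilibrium; encodes haplotype-allele
    diplotype dosages; fits a haplotype-allele GBLUP mixed model by REML; and
    evaluates prediction accuracy by repeated k-fold and forward validation
    against a SNP-based baseline. Includes quality-control filters for
    variants, individuals and phenotypes, and a founder-mosaic simulator of
    phased genotypes with blockwise linkage disequilibrium and quantitative
    traits for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
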
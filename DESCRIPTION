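Package: ukin
Title: Unbiased Kinship Estimation from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation of pairwise kinship coefficients from biallelic SNP
    dosage data. Implements the UKin unbiased kinship estimator, which removes
    the systematic negative bias of the sample-correlation genomic relationship
    matrix (scGRM) caused by treating observed allele frequencies as true
    frequencies, together with the scGRM, variance-weighted rGRM and
    KING-robust comparator estimators, closed-form bias calculators,
    relationship-degree classification, a pedigree gene-dropping genotype
    simulator with ground-truth IBD, PLINK text/binary input and output, and
    single-component REML (GREML-style) heritability estimation with
    CI-coverage experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
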
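Package: gblupad
Title: Additive and Dominance Genomic Prediction with GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for decomposing the genetic control of quantitative traits
    into additive and dominance components using genomic relationship
    matrices. Builds VanRaden additive (G) and Vitezica dominance (D)
    kernels from SNP dosages, fits BLUP, GBLUP-A and GBLUP-AD mixed models
    by average-information REML on unbalanced multi-year phenotypes, and
    derives narrow- and broad-sense heritability, the dominance ratio,
    prediction accuracy, information criteria, boundary-corrected
    likelihood-ratio tests for dominance, and k-fold cross-validated
    predictive ability. Includes a synthetic-data generator with known
    variance components for validating the estimation machinery, and
    marker quality control (call rate, minor allele frequency) with mean
    imputation for CSV and VCF genotype inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
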
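Package: clonalGBLUP
Title: Genomic and Pedigree BLUP Evaluation for Clonally Replicated Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic evaluation of clonally replicated full-sib progeny trials
    with pedigree-based and marker-based relationship matrices. Provides marker
    quality control and four missing-genotype imputation methods (stochastic by
    genotype frequency, major-homozygote replacement, and continuous gene-content
    prediction with scaled or truncated post-processing), the pedigree numerator
    relationship matrix by the tabular method, realized genomic relationship
    matrices by the allele-frequency and regression methods, restricted maximum
    likelihood variance components, BLUP and GBLUP breeding-value prediction with
    prediction-error variances and reliability-based accuracies, and
    cross-validation of genomic predictions against phenotype-only and
    pedigree-based breeding values. Includes a simulator for the full study
    design: multi-parent full-sib pedigrees, gene-dropped unlinked SNP genotypes,
    and clonally replicated multi-site phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
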
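Package: flowerGS
Title: GWAS and Genomic Selection for Flowering Time in Multi-Parent
    Doubled-Haploid Maize Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for flowering-time genetics in
    fully homozygous doubled-haploid (DH) maize panels. Provides a
    multi-parent DH population simulator with multi-environment phenotypes,
    variance-component estimation with entry-mean broad-sense heritability
    and BLUPs, genotype quality control (missing-rate and minor-allele
    frequency filters, mean imputation, principal-component covariates),
    two multi-locus association scans with pseudo-QTN conditioning and
    Bonferroni thresholding, candidate-gene retrieval in windows around
    significant SNPs, and ridge-regression BLUP (RR-BLUP) genomic
    prediction with cross-validation experiments over training-population
    size, marker density, and top-ranked GWAS markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    lme4,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
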
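Package: gsblup
Title: Genomic Selection with GBLUP: Breeding Values, SNP Effects and
    Cross-Validated Prediction Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates breeding values of inbred crop lines with the
    genomic best linear unbiased prediction (GBLUP) mixed model: a
    genomic relationship matrix from SNP dosages, AI-REML variance
    components, BLUP breeding values, ridge-equivalent back-solved
    per-SNP coefficients usable as a portable allele score file, k-fold
    cross-validated prediction accuracy with Fisher-z confidence
    intervals, and expected response to selection via the breeder's
    equation. Includes a synthetic genotype/phenotype panel generator
    emulating a small wheat diversity panel (inbred lines, array SNPs
    with local LD, replicated multi-year element-content phenotypes)
    so the full analysis is testable end to end, plus readers and
    writers for PLINK text/binary genotypes and GCTA-style GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
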
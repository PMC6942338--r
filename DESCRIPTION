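Package: axiomsnp
Title: Design, Quality Control, and Population Genetics for Axiom-Style SNP Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Pacific Northwest", "Conifer Genomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating Axiom-style fixed SNP
    genotyping arrays in species without finished reference genomes,
    such as conifers. Implements candidate-SNP filtering on 71-nt probe
    contexts, transcript and probeset ranking, and greedy
    coverage-maximizing array selection; a transparent Gaussian-mixture
    genotype caller on contrast/size intensity coordinates with per-call
    confidence scores; sample, plate, and SNP quality control with the
    seven-category SNP classification (PolyHighResolution, NoMinorHom,
    MonoHighResolution, CallRateBelowThreshold, OTV, Other, Rescued) and
    two-phase rescue protocols; per-SNP population genetic statistics
    (call rate, MAF, heterozygosity, PIC, Hardy-Weinberg chi-square);
    BLAST-based feature engineering and stepwise logistic regression
    with cross-validated ROC curves for predicting SNP conversion; and
    a seeded synthetic-data generator that emulates the statistical
    structure of a two-population array experiment so every stage can
    be exercised without proprietary raw intensity data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
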
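Package: aseqpcr
Title: Allelic Expression Profiling of GWAS Risk Loci by Real-Time qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for allele-specific expression (ASE)
    analysis of transcribed marker SNPs at GWAS risk loci using
    allele-discrimination qPCR assays (TaqMan/KASP). Covers selection of
    transcribed proxy SNPs from a candidate-variant table, calibration of
    assay sensitivity from allele-mixture dilution series, heterozygote
    genotype calling from genomic-DNA Ct pairs, gDNA-normalised delta-Ct
    (nDCt) quantification of allelic imbalance with rank-sum testing, and
    cross-tissue classification of cis-regulatory effects. Includes a
    synthetic plate generator built on an explicit exponential
    amplification model so that every stage can be verified against
    analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
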
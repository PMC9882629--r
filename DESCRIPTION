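Package: dialvax
Title: Longitudinal Vaccine-Response Transcriptomics and Serology for
    Hemodialysis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of immune response to two-dose mRNA
    vaccination in maintenance hemodialysis and control cohorts:
    negative-binomial GLM differential expression for a longitudinal
    design with subjects nested in groups (median-of-ratios size
    factors, Cox-Reid dispersion estimation with parametric trend and
    MAP shrinkage, Wald contrasts, variance-stabilizing transform);
    blood-transcription-module enrichment with family time-course
    summaries; sign-fixed module eigengenes and linear models
    predicting antibody titers; serology calculus (four-parameter
    logistic ELISA quantification, pseudovirus neutralization ID50,
    Reed-Muench TCID50); cohort-level statistics; and a synthetic
    cohort generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    minpack.lm,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    S4Vectors,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
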
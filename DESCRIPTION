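Package: parpvus
Title: Predicting PARP-Inhibitor Sensitivity of Tumors Carrying Variants of
    Unknown Significance in Homologous-Recombination Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based classification of variants of unknown significance
    (VUS) in homologous-recombination genes with respect to expected benefit
    from PARP inhibitors. Combines a second-hit (loss-of-wild-type-allele)
    score derived from variant allele frequency and pathologist-assessed tumor
    cell content with categorical PROVEAN and DANN in-silico calls and an ECOG
    Performance-Status gate, aggregates evidence to a patient-level
    Sensitive/Resistant/Uncertain label under a two-model consensus, and
    validates predictions by Kaplan-Meier progression-free-survival analysis
    dichotomized at a 120-day benefit threshold. Ships transcribed clinical
    fixture cohorts, a seeded synthetic-cohort generator with a binomial
    read-depth noise model, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
biocViews: Software, VariantAnnotation, Classification, Survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
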
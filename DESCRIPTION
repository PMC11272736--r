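Package: endotype
Title: Molecular Subtyping of Endometrial Cancer from Whole-Exome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines endometrial-cancer molecular subtypes from paired
    tumor/normal whole-exome sequencing using a single-method cascade:
    a mutational-spectrum rule for POLE-ultramutated tumors, a tumor-versus-normal
    microsatellite repeat-length stepwise-difference score for MSI-H calling,
    and a Gaussian Naive Bayes predictor of the TCGA serous-like copy-number
    cluster built on per-sample copy-number features. Both the TCGA-analogue
    (POLE / MSI / CN low / CN high) and the surrogate-marker analogue
    (POLEmut / dMMR / NSMP / p53abn) classifications are produced, together
    with sequencing-quality plausibility flags for MSI calls, IHC concordance
    tables, and Kaplan-Meier / log-rank / Cox evaluation of the resulting risk
    strata. Includes a seeded synthetic tumor/normal cohort generator with
    planted subtype signals and subtype-dependent survival for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    vcfR
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
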
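Package: drugrepos
Title: Multi-Cohort Disease Signatures, Signature-Reversal Drug
    Repositioning, and Target-Trial Survival Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for computational drug repositioning from
    transcriptomic and observational clinical data. Discovers robust
    disease gene signatures by random-effects meta-analysis of Hedges' g
    effect sizes across independent expression cohorts with
    leave-one-dataset-out filtering, ranks candidate drugs by inverse
    Pearson correlation of their perturbation profiles with the disease
    signature, tests signature enrichment against gene-set collections,
    and validates candidate drugs with target-trial-style retrospective
    cohort analyses (Cox proportional hazards, propensity matching,
    negative-control outcomes). Includes synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    survival,
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
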
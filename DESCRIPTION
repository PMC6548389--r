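Package: pepanel
Title: Longitudinal Plasma Proteomics Panels for Early Preeclampsia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal case-control plasma proteomics
    studies of early preeclampsia. Converts repeated gestational-age-indexed
    protein abundances to multiples-of-the-mean (MoM) values via cubic-spline
    linear mixed-effects reference curves fitted on normal pregnancies, ranks
    markers by the partial area under the ROC curve (FPR < 0.5) from
    leave-one-patient-out linear discriminant scores, selects parsimonious
    panels of up to five proteins under a +0.01 pAUC acceptance rule,
    estimates out-of-sample performance by stratified bootstrap and repeated
    3-fold cross-validation with selection nested inside the training loop,
    tests covariate-adjusted differential abundance with empirical-Bayes
    moderated t-statistics, and performs over-representation analysis of
    significant proteins against the assay panel background. Includes a
    synthetic longitudinal cohort generator with planted markers and
    closed-form oracle AUCs so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    splines,
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pROC,
    limma,
    optparse
Config/testthat/edition: 3
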
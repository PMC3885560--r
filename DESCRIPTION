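Package: ogttmetab
Title: Longitudinal OGTT Metabolomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal oral glucose tolerance test
    (OGTT) plasma metabolomics in a pre/post intervention cohort design:
    presence filtering and sum-intensity normalization, transform-to-normality
    selection by the Anderson-Darling statistic, clinical insulin-sensitivity
    indices (Matsuda, QUICKI, HOMA), incremental post-OGTT area-under-the-curve
    excursions with one-sample testing, per-metabolite random-intercept mixed
    models with Benjamini-Hochberg false-discovery-rate control, NIPALS PLS-DA
    with leave-one-out cross-validation, jackknife weight-based feature
    selection and permutation validation (Q2, RMSEP, AUROC), Tanimoto
    chemical-similarity networks, and loading-prefiltered Spearman
    cross-correlation. Includes a synthetic-cohort generator with planted
    ground truth so every stage is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nortest,
    pROC,
    pracma,
    withr
Config/testthat/edition: 3
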
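Package: aldpanel
Title: Plasma Proteomic Biomarker Panel Discovery for Alcohol-Related Liver Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering and evaluating plasma
    proteomic biomarker panels against liver histology in alcohol-related
    liver disease. Covers matrix quality control and downshifted-normal
    (missing-not-at-random) imputation, covariate-adjusted differential
    abundance (ANCOVA) and Spearman partial correlation screens with
    Benjamini-Hochberg control, paired liver-plasma integration, minimum
    redundancy-maximum relevance panel selection with missingness-stratified
    repeated cross-validation, benchmarking against clinical comparator
    tests (DeLong's test for correlated ROC curves, categorical net
    reclassification improvement), and prognostic evaluation of panel risk
    scores (Harrell's concordance index, fixed-horizon AUC). Ships a
    synthetic-cohort generator with planted ground truth so the whole
    pipeline can be exercised and audited end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, survival, pROC, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
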
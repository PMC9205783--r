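# aldpanel

Plasma proteomic biomarker-panel discovery and evaluation for
alcohol-related liver disease (ALD).

Liver biopsy remains the reference standard for staging fibrosis,
inflammatory activity and steatosis in ALD, but it is invasive and poorly
suited to screening. `aldpanel` implements, as a tested and reusable R
pipeline, the full analysis path from a DIA mass-spectrometry protein ×
sample intensity matrix to validated multi-protein diagnostic panels and
their prognostic evaluation:

1. **Preprocessing** — proteome-depth filter (≥200 quantified proteins per
   sample), 60% valid-value filter, log2 transform, QC-replicate CV filter
   (CV ≤ 0.30 on linear intensities), and *downshifted-normal imputation* of
   missing-not-at-random dropout: each missing cell in sample *s* is drawn
   from N(m_s − 1.8·d_s, (0.3·d_s)²), where m_s and d_s are the mean and SD
   of the sample's observed log2 intensities.
2. **Differential screens** — per-protein ANCOVA of log2 intensity on the
   histology stage (categorical) adjusted for age, BMI, sex, abstinence and
   the competing histology axis, with Benjamini–Hochberg FDR; and Spearman
   *partial* correlation against histology scores (significant at q < 0.05
   and |r| ≥ 0.3).
3. **Liver–plasma integration** — paired Pearson correlation across
   compartments, co-dysregulation calls (concordant/discordant), and
   annotation-category fractions (liver-specific / secreted).
4. **Panel selection and validation** — minimum-redundancy–maximum-relevance
   (mRMR, F-statistic / mean |Pearson r| quotient) feature ranking inside
   each training fold, L2-penalized logistic panel models, 5-fold × 10-repeat
   cross-validation stratified jointly on class and *missingness pattern* of
   the clinical comparator tests, the "maximal F1 with the minimal panel"
   size rule, and a frozen final train–test model.
5. **Benchmarking** — comparator tests at fixed clinical cutoffs, DeLong's
   test for correlated ROC curves (placement-value covariance, midranks),
   categorical net reclassification improvement
   NRI = [P(up|event) − P(down|event)] + [P(down|nonevent) − P(up|nonevent)],
   and rule-out accuracy in low-incidence populations.
6. **Prognosis** — composite liver-related-event endpoint, Harrell's C-index
   and fixed-horizon (3/5-year) ROC-AUC of the *diagnostic* panel's risk
   score, without refitting on outcomes.

Patient-level data from the original cohorts are access-restricted, so the
package ships a **synthetic-cohort generator** (`generate_cohort()`) that
emulates the published cohort structure — exact fibrosis-stage counts
36/124/106/27/67 (F0–F4) in 360 biopsied patients, correlated
inflammation/steatosis scores through a Gaussian copula, planted
stage-responsive marker proteins, abundance-dependent (MNAR) dropout, paired
liver subsets, comparator availability patterns, and right-censored
outcomes — together with a ground-truth record so every stage of the
pipeline can be audited for recovery and calibration.

## Worked example

```r
library(aldpanel)

# a synthetic ALD cohort with 9 planted markers per histology axis
sim <- generate_cohort(cohort_config(seed = 1))
table(label_endpoint(sim$meta, "F2"))
#> control    case
#>     160     200

# MNAR dropout + preprocessing back to a complete log2 matrix
cfg <- cohort_config(seed = 1)
raw  <- apply_mnar_dropout(sim$plasma, cfg$mnar_midpoint, cfg$mnar_steepness, seed = 2)
proc <- preprocess_pipeline(delog2_transform(raw), generate_qc_replicates(cfg),
                            impute = impute_params(seed = 3))

# differential screen against fibrosis
sp <- spearman_partial_scores(proc, sim$meta, "fibrosis")
sum(sp$significant)
#> [1] 16

# nine-protein panel for significant fibrosis (>= F2)
X   <- t(proc$values)
lab <- label_endpoint(sim$meta, "F2")
fin <- final_fit(X[!is.na(lab), ], lab[!is.na(lab)], k_star = 9,
                 seed = 4, endpoint = "F2")
round(fin$metrics, 3)
#> precision  recall    f1  balanced_accuracy  roc_auc
#>     0.921   0.875 0.897              0.891    0.963
```

The held-out ROC-AUC of ~0.96 reflects the strong planted signal
(0.5 log2-units per stage against 0.5 SD noise); the closed-form Bayes AUC
of the complete-data construction is 0.993, so even after MNAR dropout and
imputation the pipeline recovers most of the available discrimination. The whole flow is also available as staged
commands (`cmd_simulate()`, `cmd_run()`) or from the shell via
`inst/scripts/ald-pipeline.R`.

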
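---
title: "Methods: proteomic panel discovery and evaluation in ALD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic panel discovery and evaluation in ALD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldpanel)
```

## The problem

In alcohol-related liver disease (ALD), three histological lesions —
fibrosis (Kleiner F0–4), inflammatory activity (I0–5, the sum of lobular
inflammation 0–3 and hepatocyte ballooning 0–2) and steatosis (S0–3) — are
staged by biopsy. `aldpanel` builds and evaluates plasma-protein panels
that detect these lesions non-invasively from DIA mass-spectrometry
intensity matrices, and then asks whether the same diagnostic panels carry
prognostic information about liver-related events (LREs) and death.

The binary endpoints are significant fibrosis (F2: Kleiner ≥ 2), advanced
fibrosis (F3: ≥ 3), mild inflammatory activity (I2: activity ≥ 2) and any
steatosis (S1: ≥ 1). Samples with a missing score are unlabeled, never
silently controls.

## Preprocessing model

DIA proteomics matrices are missing-not-at-random: low-abundance proteins
drop out preferentially. The pipeline order is fixed:

1. sample depth filter (≥ 200 quantified proteins),
2. valid-value filter (protein present in ≥ 60% of samples, boundary kept),
3. log2 transform,
4. QC-replicate CV filter (CV = SD/mean of *linear* intensities across QC
   injections; proteins with CV > 0.30, or fewer than two observed QC
   values, are removed and reported),
5. downshifted-normal imputation.

Imputation draws each missing cell of sample $s$ from
$\mathcal N(m_s - 1.8\,d_s,\ (0.3\,d_s)^2)$ with $m_s, d_s$ the mean and SD
of that sample's *observed* log2 values (no iterative refinement; $d_s$ uses
the $n-1$ denominator). The 1.8/0.3 defaults are the standard
Perseus-style parameters for MNAR dropout. Computing the QC CV on the linear
scale is the conventional definition; where a log2 matrix reaches the filter
it is de-logged internally for the CV only. The valid-value fraction is
pooled over all samples, not per group. Whether the depth filter should
precede the valid-value filter is not decidable from first principles; the
order above is fixed and idempotent apart from fresh imputation draws.

## Differential screens

Per protein, an ANCOVA compares a full OLS model — log2 intensity on the
histology factor encoded categorically (one indicator per stage above
baseline) plus covariates — against the covariates-only reduced model with a
partial $F$-test, $F = \frac{(RSS_r - RSS_f)/\Delta df}{RSS_f/df_f}$.
Covariates are age, BMI, sex and abstinence, plus the competing histology
axis entered *numerically*: steatosis when testing fibrosis or inflammation,
and fibrosis (only) when testing steatosis — the narrower reading of a
reciprocal-adjustment protocol; both the set and the reading are
configurable. Stage levels with fewer than two samples are merged downward
with a warning; rank-deficient designs are a hard error naming the collinear
columns. Multiplicity is controlled by Benjamini–Hochberg (own step-up
implementation, cross-checked against `p.adjust` in the tests) at q < 0.05.

The correlation screen is a Spearman *partial* correlation: intensities,
score and numeric covariates are rank-transformed (average ranks), both
ranked intensity and ranked score are residualized on the ranked covariate
block, and $r$ is the Pearson correlation of residuals with
$df = n - 2 - k$. A protein is a hit iff q < 0.05 **and** $|r| \ge 0.3$ —
the effect-size gate matters more than the p-value at n = 360.

## Panel selection and honest cross-validation

The mRMR variant is fixed deliberately: relevance is the one-way ANOVA
F-statistic against the binary label, redundancy the mean $|r|$ against the
already-selected set, and the greedy criterion their quotient with
$\varepsilon = 0.001$ guarding the denominator; ties break lexicographically
so rankings are reproducible. "mRMR" has mutual-information variants; this
package implements only the F/|r| quotient scheme.

The classifier is L2-penalized logistic regression (penalty
$\tfrac{1}{2C}\lVert\beta\rVert^2$, $C = 1$, intercept unpenalized) fitted
by damped Newton iterations to gradient norm $<10^{-6}$, on features
standardized within the training data; the scaler travels with the model. A
probability equal to the 0.5 cutoff classifies as case.

Cross-validation is 5-fold, repeated 10 times, stratified jointly on the
class label and the *missingness pattern* of the considered clinical
comparator variables (patterns rarer than the fold count pool into a `rare`
stratum), dealing each stratum round-robin so per-fold class counts differ
by at most one. Two honesty decisions depart from common shortcuts:

* the mRMR ranking is recomputed **inside each training fold** for the
  panel-size curve (a single global ranking before CV leaks test
  information; that legacy protocol remains available via
  `legacy_global_ranking = TRUE`), and
* a label-permutation audit is part of the acceptance suite: with permuted
  labels the cross-validated AUC must stay within [0.45, 0.55].

The panel size is the smallest k attaining the maximal mean F1 across the 50
splits; the final model is fitted on a stratified 80/20 split and frozen for
benchmarking, rule-out and prognosis. CI aggregation across splits uses the
normal approximation mean ± 1.96·SD/√50.

## Benchmarking statistics

Comparator tests are evaluated at fixed clinical cutoffs (≥ semantics on the
case side; cutoffs are configuration, not code) on the subset with available
values. DeLong's test uses midrank placement values, so tied probabilities —
frequent from small logistic panels — are handled; identical predictors
return z = 0, p = 1 rather than erroring. The categorical NRI follows the
event/nonevent decomposition
$\mathrm{NRI} = [P(\mathrm{up}\mid e) - P(\mathrm{down}\mid e)] +
[P(\mathrm{down}\mid ne) - P(\mathrm{up}\mid ne)]$ on binary calls at the
stated cutoffs (not the continuous NRI).

## Prognostic evaluation

The composite LRE endpoint takes the earliest qualifying event from a
configurable list of ten clinical outcomes (alcoholic hepatitis through
jaundice due to liver failure); the published composite's exact cardinality
is ambiguous (ten named outcomes vs. a stated eleven types), which is why the
list is configuration. Harrell's C counts all comparable pairs — the smaller
observed time must belong to an event; tied times are non-comparable unless
exactly one is an event — with half credit for risk ties. The fixed-horizon
AUC uses the simple exclusion rule (cases: event ≤ horizon; controls:
observed past the horizon; early censored excluded) rather than IPCW
weighting; the estimator is isolated so an IPCW variant can be added. The
risk score is always the frozen *diagnostic* model's probability — no
refitting on outcomes.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the published derivation-cohort composition
exactly: 360 biopsied patients with fibrosis counts 36/124/106/27/67, NAS
scores for 352 of them with activity counts 72/91/82/53/31/23 and steatosis
156/85/72/39. (The published text also prints "200 controls / 160 cases"
for ≥F2, which contradicts its own stage table; this package trusts the
stage distribution, under which ≥F2 yields 200 cases, consistent with the
stated 56% prevalence of significant fibrosis. The same applies to the I2
control count.) Scores are coupled through a latent Gaussian copula
(Spearman 0.6 fibrosis–inflammation, 0.3 fibrosis–steatosis — free defaults
chosen so that fibrosis and inflammation hit lists overlap strongly, as
observed in practice). Protein baselines span a 12-log2-unit dynamic range
(a free choice; the published dynamic range is not stated). Planted markers
(9 per axis by default) respond at 0.5 log2-units per stage step with
residual SD 0.5 — effects large enough that recovery failures indicate
pipeline defects rather than sampling noise. Ballooning and lobular
inflammation are derived deterministically from the activity score
(b = min(2, round(0.4·a))), so their marginals are approximate while the
activity marginal is exact. Comparators are noisy monotone transforms of the
relevant score (kPa-like for elastography, index-like otherwise) with
availability patterns drawn from a small set — enough to exercise
fixed-cutoff benchmarking and missingness stratification without claiming
clinical realism. Outcomes are exponential with hazard
$h_0 e^{0.65 \cdot \mathrm{stage}}$, $h_0 = 0.001$/month, administratively
censored at 72 months, giving roughly a quarter of patients an LRE —
plausible for a biopsied ALD cohort with majority significant fibrosis;
death uses a halved stage coefficient. All randomness fans out from one
master seed through named substreams (histology, covariates, proteome,
liver, comparators, outcomes, dropout), so any component can be regenerated
independently.

Not emulated: peptide-level structure, batch effects, instrument drift,
protein–protein correlation beyond the planted axes, non-proportional
hazards, or informative censoring. Passing recovery tests therefore shows
the pipeline is correct and calibrated under its stated model — not that
the headline accuracies would transfer to real cohorts, whose patient-level
data remain access-restricted.

## Numerical choices and degenerate inputs

* Ordinal scores are small integers with out-of-band missingness (never −1).
* Linear intensities must be strictly positive; log2/linear conversion is
  exact and guarded against double transformation.
* A sample with fewer than two observed values cannot be imputed (SD
  undefined) and is a hard error.
* mRMR ties break by feature id; constant features have zero relevance and
  are selected last.
* The Newton logistic solver damps steps by halving until the penalized
  deviance does not increase, and hard-errors after 10⁴ iterations.
* `select_panel_size` resolves F1 ties toward the smaller panel.
* DeLong with zero variance of the difference returns the null result.
* Degenerate metric inputs (single-class truth, empty significant sets, no
  comparable pairs, no cases past the horizon) report missing values with
  warnings rather than fabricating numbers.

## Problem sizes used in the checks

The acceptance suite runs the screens on 500-protein, 360-patient cohorts
(10 null seeds for FDR calibration, 5 signal seeds for recovery), 2,000
null replicates for the DeLong type-I rate, 10 permutation seeds for the
leakage audit, and 10,000 imputed cells for the moment contract — sizes at
which Monte-Carlo error is small relative to every asserted tolerance while
the whole suite stays fast. The held-out panel AUC is compared against the
closed-form Bayes AUC of the planted Gaussian construction; that reference
assumes complete matrices, so the recovery experiment runs without MNAR
dropout (the dropout-plus-imputation path is exercised and checked
separately).
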
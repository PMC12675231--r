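---
title: "Methods: phenotyping, spline dose-response and leakage-free validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, spline dose-response and leakage-free validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenospline)
```

This vignette documents the models implemented by `phenospline`, the
assumptions behind them, the tunable parameters that matter, and the
numerical choices made where conventions differ. It states no empirical
result beyond what the package's own tests compute.

## The scientific setting

Adults are classified into four metabolic obesity phenotypes from BMI
and two insulin-resistance / liver-fat indices. Two hormones move in
opposite directions across that spectrum: plasma oxytocin falls and
leptin rises from metabolically healthy normal weight (MHNW) to
metabolically unhealthy obesity (MUO). Disordered-eating severity is
scored by questionnaires (EDE-Q, DEBQ, EBA-O), with an elevated global
EDE-Q score (>= 2.5) as the binary outcome of the predictive models.
The package asks three questions: do hormones and severity differ
across phenotypes; which markers are independently associated with
severity; and how well does the biomarker predict the outcome out of
sample, alone and combined with metabolic context.

## The synthetic cohort generator

Cohorts of this design are rarely public, so the generator is the
package's reference input and is first-class, tested code. It emulates:

- a four-component phenotype mixture with probabilities 18/99, 12/99,
  13/99, 56/99 and 76.8% female, the composition of a typical
  single-center cohort of 99;
- right-skewed hormones and labs, generated log-normally **conditional
  on phenotype**. Phenotype labels are drawn first and are ground
  truth; `classify_phenotype()` is intentionally *not* re-applied to
  overwrite them — agreement between generated biometrics and the
  classifier is a separate test;
- per-phenotype medians anchored to published cohort-level
  descriptives (overall medians near: glucose 5.1 mmol/L, insulin
  13.2 uU/mL, ALT/AST 21 U/L, TC 4.81, HDL 1.17, TG 1.15 mmol/L,
  oxytocin 37.6 pg/mL, leptin about 1.16 ng/mL). Leptin is generated
  in ng/mL throughout; published unit usage for leptin is
  inconsistent, and the package standardizes on ng/mL rather than
  reconciling sources;
- a latent severity scale
  `S = 1.0 z(log leptin) - 0.30 z(log oxytocin) + N(0, 0.40)`,
  where `z` standardizes with the *theoretical* mixture moments implied
  by the configuration (not sample moments), so severity is a
  per-participant quantity independent of cohort size. The global
  EDE-Q score is the logistic squashing `6 plogis(-0.0377 + S)`;
- the twelve subscales as the global score plus independent noise,
  re-clipped to instrument ranges (EDE-Q/EBA-O 0-6, DEBQ 1-5), which
  reproduces the strong subscale intercorrelation with minimal
  parameters.

The three severity constants were calibrated once by large-n
simulation (4 x 10^5 draws) against three targets — Spearman rho of
about -0.73 (oxytocin vs global EDE-Q) and +0.92 (leptin vs global
EDE-Q), and outcome prevalence 0.64 — and then frozen. The anchor
-0.0377 is `logit(2.5/6)` minus the 36th percentile of the latent
severity distribution, which places the prevalence at its target by
construction. These defaults are the study conditions; they are not
adjusted per analysis.

What the generator does **not** emulate: assay noise, menstrual-phase
or medication effects, informative missingness, or real questionnaire
item structure. Tests passing on synthetic cohorts therefore
demonstrate the correctness of the statistical machinery under the
assumed data-generating process, not clinical validity on real data.

`generate_known_truth()` swaps the questionnaire-derived outcome for a
Bernoulli draw from an explicit probability law of the biomarker
(monotone logistic, U-shaped, or flat) and returns the truth object,
enabling recovery tests of the dose-response and cutoff-inversion
machinery against a known crossing.

## Metabolic indices and phenotyping

HOMA-IR, HSI and VAI follow their standard published formulas; the
atherogenic index is computed as `(TC - HDL)/HDL`, the most common
definition consistent with typical reported magnitudes, and documented
here as an assumption. The phenotype grid defines "metabolically
unhealthy" as HOMA-IR >= 2.5 (conventional adult bound) **or**
HSI >= 36 (the standard NAFLD-risk bound); BMI classes are
18.5-24.9 / 25-29.9 / >= 30. Exact cutoff sets vary between studies
and supplementary definitions are not always available; these choices
are explicit substitutes. Metabolically healthy overweight/obese
participants do not fit any of the four phenotypes and are labelled
`unclassified`, excluded from four-group analyses. The unhealthy flag
is BMI-independent by construction.

## Group statistics and association models

The descriptive summary gates each variable on Shapiro-Wilk at
alpha = 0.05 (mean +/- SD when not rejected, otherwise median and
type-7 IQR — linear-interpolation quantiles, stated explicitly because
quantile conventions differ). Kruskal-Wallis uses the tie-corrected H
with a chi-square reference; Dunn's z uses the tie-corrected pooled
variance, with average ranks throughout. Both Bonferroni (the default,
matching the primary post hoc convention) and Benjamini-Hochberg
adjustments are available; the variable-family FDR is always BH, and
the family size used is reported alongside the q-values. Missing data:
pairwise-complete for correlations, listwise within each test.

OLS inference uses HC3 sandwich covariance with a t reference on
n - p degrees of freedom (a small-sample convention). Backward
elimination drops the largest-p predictor at or above 0.10 and refits;
a p exactly at the threshold is dropped, so every retained predictor
satisfies the strict inequality. With distinct p-values the procedure
is invariant to candidate ordering. PCA components are computed on
internally standardized variables and sign-oriented so each component
correlates non-negatively with the mean of its inputs, making scores
reproducible across platforms.

## Restricted cubic splines and the dose-response curve

The RCS basis uses k knots (default 4, configurable 3-5) at quantile
probabilities (0.05, 0.35, 0.65, 0.95), with the standard truncated-
power construction scaled by `(t_k - t_1)^2` for conditioning; the
scaling changes coefficients but not fitted probabilities. The basis
is linear beyond the boundary knots with continuous first and second
derivatives (both verified numerically in tests). When the data have
exactly k distinct values those values are the knots. Fitting is
IRLS maximum likelihood with a tight tolerance; convergence is
declared when the score norm falls below 1e-6, and separation is
flagged (standardized coefficient magnitude > 15 or perfect in-sample
classification) with a warning, since small-sample spline logistic
models are separation-prone.

The dose-response curve is fitted on the full sample; bootstrap bands
are pointwise percentile intervals over case-resampled refits with
**knots held fixed** at the point-estimate placement, i.e. the band is
conditional on the knot locations. Replicates that fail to refit are
dropped and counted. Bands are clipped to contain the point estimate,
so `lower <= fit <= upper` holds by construction at every grid point.
Outside the observed support the bands widen; the curve is reported
there but not interpreted.

## Nested cross-validation without leakage

The fold plan is a stratified outer 5-fold partition (per-fold event
counts within 1 of proportionality; remainders placed to balance
total fold sizes), with stratified inner 5-folds inside each
outer-training set. Everything learned from data — imputation medians,
centering/scaling constants, spline knots, PCA loadings, and the
elastic-net `(lambda, alpha)` — is computed on training rows only;
held-out rows are scored through stored constants. Inner tuning refits
the preprocessing inside each inner-training split as well. The
leakage contract is tested literally: corrupting outer-test rows
before fold fitting leaves every learned parameter bit-identical.

The combined model's penalty is tuned over alpha in {0.1, ..., 1.0}
and 50 log-spaced lambda values from the data-derived lambda_max down
to lambda_max x 1e-4, selecting by mean inner-fold AUC —
discrimination-first tuning, consistent with reporting AUC as the
headline metric (and with the known tendency of such tuning to leave
the winning model miscalibrated, which the recalibration module
measures rather than hides). Median imputation is used because the
skewed labs make the mean a poor fill-in. The EDE-Q PCA component
(one component, computed on the four subscales, excluding the global
score) summarizes subscales of the instrument that also defines the
outcome; this circularity is preserved deliberately because it
mirrors the published combined model, and `model_spec(include_edeq_component
= FALSE)` exposes the non-circular alternative.

OOF probabilities are pooled across folds before ROC construction
(the alternative — per-fold averaging — is not implemented, since
threshold selection on pooled OOF predictions is the stated use).

## Evaluation and the biomarker cutoff

AUC is the Mann-Whitney estimator computed from average ranks, exactly
equal to all-pairs concordance with half credit for ties. The Youden
point maximizes sensitivity + specificity - 1 over observed prediction
values, breaking ties toward higher specificity; its bootstrap CIs
re-estimate the threshold within each replicate. The paired AUC
difference uses B case resamples scoring both models on the same
resample, a percentile CI, and a two-sided bootstrap p with a +1
continuity correction (so a model compared with itself reports
delta = 0 and p = 1). Recalibration follows the standard two-fit
convention: slope from a logistic refit on `logit(p_hat)`, intercept
from a refit with `logit(p_hat)` as a fixed offset; probabilities are
clipped at 1e-6 before the logit.

Cutoff inversion finds all crossings of the fitted curve with the
probability threshold by sign change plus linear interpolation on a
200-point grid. The *selected* crossing is the smallest biomarker
value where the curve falls from above to below the threshold — the
down-crossing, because low biomarker means high risk in this setting;
for U-shaped curves all crossings are still reported. The CI is the
percentile interval of the selected crossing across the bootstrap
replicate curves; replicates without a down-crossing are counted and
excluded, and an absent crossing in the point estimate is a flagged
empty result, not an error. Percentile (not BCa) intervals are used
everywhere for simplicity and determinism, with B = 2000 by default
and smaller B in tests.

Decision curves use the standard net-benefit formula on a 0.05-0.95
threshold grid (step 0.01), with treat-all and treat-none references
and the cohort prevalence marked.

## Problem sizes used by the test suite

Calibration-level checks run on one n = 5000 cohort and 100
study-sized (n = 99) cohorts; cutoff recovery uses 100 seeds at
n = 1000 with B = 200 bootstrap refits; the permutation null uses 50
outcome shuffles at n = 99. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping the default
suite fast.

## Known limitations

- The generator's subscale model is a single-factor structure plus
  noise; it does not reproduce instrument-specific factor structure.
- Phenotype cutoffs are conventional substitutes, not a validated
  consensus definition.
- The bootstrap bands condition on knot placement; uncertainty in the
  knots themselves is not propagated.
- At n = 99 the operating point and its biomarker crossing vary
  substantially across seeds; they are exploratory statistics.
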
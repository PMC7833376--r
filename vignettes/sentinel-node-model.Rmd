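---
title: "A multiplicative exponential model for sentinel lymph node positivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiplicative exponential model for sentinel lymph node positivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnrisk)
```

## The clinical problem

In early breast cancer with no nodal abnormality on clinical examination or
imaging (cN0), guidelines still call for sentinel lymph node biopsy during
surgery, an invasive and costly procedure whose result is negative for
roughly four patients in five. A pre-operative estimate of the probability
that the sentinel node is metastatic could help prioritise who truly needs
the biopsy. `slnrisk` implements the risk model used by open lymph-node
involvement calculators for this purpose, its population calibration
procedure, and the evaluation protocol used to judge whether such a model is
clinically usable.

## The model

For a patient with primary tumour diameter $D$ (mm) and discrete prognostic
factors (age class, histologic type, ER, PR, histological grade, optionally
Ki67 and HER2), the probability that the sentinel node is positive is

$$ L_n \;=\; 1 - \exp\!\Big(-\,Q_n \prod_i g_i \, D^{Z}\Big), $$

where $g_i$ is the multiplier attached to the patient's level on factor
$i$, $Q_n$ is an interpolation parameter for the whole population, and the
exponent $Z$ is fixed at 1 for lymph-node involvement. The form can be read
as a survival-of-seeding argument: the tumour sheds cells at a rate
proportional to its size, each factor scales that rate multiplicatively,
and the node stays negative only if no seeding event succeeds.

Two structural conventions matter:

* **Missing data.** A record whose raw value is unknown on some factor maps
  to the reserved level `"unknown"`, which always carries $g = 1$: missing
  information must not move the prediction. `"unknown"` levels are never
  fitted.
* **Bounds.** $0 \le L_n < 1$ for every finite parameter set; the
  implementation refuses to return a probability that would round to 1.0
  rather than doing so silently (see *Numerical choices* for the one
  documented exception).

## Two-phase calibration

The parameters are not estimated by maximum likelihood but by moment
matching, in two phases (`sln_fit()`):

1. **Phase 1** (`fit_qn()`): with every $g_i = 1$, solve for the unique
   $Q_n > 0$ such that the mean predicted probability over the training
   cohort equals the observed node-positive fraction. The mean prediction
   is continuous and strictly increasing in $Q_n$, so the root exists and
   is unique whenever the cohort contains both classes.
2. **Phase 2** (`fit_factor_parameter()`): with $Q_n$ fixed, for each
   non-unknown level of each factor solve for the $g > 0$ that equates the
   mean prediction with the observed rate *within that level's stratum* (of
   size $W$). Every level is fitted independently, against the Phase-1
   baseline only — each factor is treated as a statistically independent
   cause, and no joint refinement or sequential conditioning is performed.

Identifiability comes from the ordering: $Q_n$ absorbs the population mean
first, so the $g$ are interpretable as within-level deviations from the
population baseline; no reference category is needed and none is used.
$Q_n$ is *not* re-normalised after Phase 2, so the mean prediction of the
final model need not equal the prevalence exactly; the calibration
identities that do hold to solver tolerance are the Phase-1 identity (all
$g = 1$) and the per-stratum Phase-2 identities, and the test suite asserts
both at $10^{-9}$.

A useful consequence of independence is consistency under a balanced
design: if the data are generated by the model with a single active factor
whose multipliers average close to 1, Phase 1 recovers approximately
$Q_n^\ast \cdot \mathrm{E}[g^\ast]$ (with a second-order convexity
correction well under 1% at the rates seen here) and Phase 2 then recovers
each $g^\ast$ up to the same factor. The parameter-recovery test uses
$g^\ast = (0.8, 1.0, 1.25)$ on equal thirds with $Q_n^\ast = 0.022$ at
$n = 20{,}000$, where both bias terms and sampling noise sit comfortably
inside 5% for $Q_n$ and 10% for each $g$.

## Feature variants

Variant A is the base calculator feature set (age class, histologic type,
ER, PR, grade); variant B adds HER2, variant C adds Ki67, and variant D
adds both (`variant_features()`). HER2 and Ki67 are candidates because the
factors they correlate with (histology and grade respectively) are the ones
with substantial missingness in the motivating cohort.

## Evaluation protocol

* **AUC** (`roc_auc()`): the Mann–Whitney estimator,
  $P(\text{score}_+ > \text{score}_-) + \tfrac12 P(\text{tie})$, identical
  to the trapezoidal area under the empirical ROC curve.
* **Threshold** (`youden_threshold()`): maximise Youden's
  $J = \text{sensitivity} + \text{specificity} - 1$ over the candidate set
  of observed scores, for the rule score $\ge t \Rightarrow$ positive.
  Ties in $J$ break toward higher sensitivity, then the smaller threshold —
  in a screening context the false negative is the costlier error.
* **Confusion metrics** (`confusion_metrics()`): accuracy
  $(TP+TN)/(TP+TN+FP+FN)$, sensitivity $TP/(TP+FN)$, specificity
  $TN/(TN+FP)$, held exactly as identities of the counts.
* **Hold-out split** (`holdout_split()`): simple random, training size
  $\lceil 0.8\,n \rceil$ (795 of 993). It is deliberately *not*
  class-stratified: the class counts this protocol is modelled on are not
  proportional to a stratified 80% split, so stratification is not forced.
* **Repeated cross-validation** (`repeated_cv()`): `n_rounds` independent
  rounds of class-stratified `n_folds`-fold CV; within a round every record
  is scored exactly once by a model fitted without it, the round's
  out-of-fold scores are **pooled**, and AUC / Youden threshold / confusion
  metrics are computed once per round on the pool. Pooling is chosen over
  per-fold averaging because a Youden threshold chosen on a single ~80
  record fold is unstable. Medians and quartiles over rounds use the
  linear-interpolation convention (R's default quantile type 7). Round $r$
  uses seed `base_seed + r - 1`, making the whole object bit-reproducible.
* **Threshold transfer**: in `run_experiment()` the Youden threshold is
  selected once on the full training set scored by the model refitted on
  the full training set, then applied unchanged to the held-out test set
  and to every subgroup. Subgroup rows (`stratified_performance()`):
  overall, T1/T2 size categories, age $\le 45$ / 45–60 / $> 60$ (a coarser
  binning than the model's decade classes, configured independently),
  grades G1–G3, and the four St. Gallen molecular subtypes derived from
  ER/PR/HER2/Ki67 with Ki67 dichotomised at 20%. Subgroups with no
  positives (or no negatives) report `NA` rather than a fabricated rate.

## The synthetic cohort generator

The institutional data the protocol was designed around are not public, so
`generate_cohort()` emulates them from their published aggregate structure:

* **Categorical marginals** equal the printed per-level frequencies of the
  993-patient cohort, including the missingness pattern (grading ~60%
  unknown, histology ~21% unknown, HER2 ~0.6% unknown). Missingness is
  completely at random — no mechanism was published.
* **Diameter** is log-normal (meanlog 2.580, sdlog 0.607), truncated at
  120 mm and rounded to 0.1 mm; these values reproduce the printed
  75.3 / 23.3 / 1.4% T1/T2/T3 split. Ages are uniform within their decade
  bin.
* **Outcome law**: node status is Bernoulli at the model probability under
  ground-truth parameters. The default multipliers echo the published
  within-level positivity pattern (e.g. higher positivity at ages 41–50
  and in lobular and higher-grade tumours, lower in ER-negative records),
  and $Q_n$ is solved numerically — by quadrature over the covariate law
  (`expected_prevalence()`) — so the expected positive rate is 0.2095, the
  published overall rate.
* **Independence**: covariates are sampled independently. The real cohort
  certainly has correlations (grade × Ki67, age × subtype, ...), but only
  marginals were published, and only marginal fidelity is claimed. Passing
  tests on these cohorts therefore demonstrate the *mechanics* of
  calibration and evaluation, not clinical transportability: the published
  performance tables themselves remain out of reach without the
  institutional data, and the package makes no attempt to reproduce their
  exact values.

## Numerical choices

* Root solving: geometric bracket expansion, Brent's method, then verified
  to an absolute tolerance of $10^{-10}$ on the rate mismatch, with a
  bisection fallback capped at 200 iterations; fitting is fully
  deterministic.
* Degenerate strata: an observed rate of exactly 0 or 1 has no finite
  root; $g$ is clamped to $10^{-6}$ / $10^{6}$ and flagged. Strata smaller
  than `min_stratum` (default $W \ge 5$) keep $g = 1$ with a warning.
* Saturation: $1-\exp(-\eta)$ rounds to 1.0 in double precision once
  $\eta \gtrsim 36.7$. For an unclamped parameter set that is treated as an
  input error and raised; for a parameter set carrying a clamp-bound $g$
  the saturated value *is* the moment-matched rate of the degenerate
  stratum, so prediction is allowed to return it (otherwise
  cross-validation could not score folds containing a small all-positive
  stratum).
* Percentages in summaries are rounded to 2 decimals, half away from zero;
  probabilities themselves are never rounded or clipped.
* Parameter and configuration JSON is written with 17 significant digits,
  so serialisation round-trips doubles exactly.

## Problem sizes

The test suite runs the randomized calibration-identity suite at 20 cohorts
of $n = 500$, parameter recovery at $n = 20{,}000$, oracle-equivalence
checks on 100 random instances of $n \le 100$, CV contracts at 5 rounds ×
10 folds on $n = 2{,}000$, and marginal-convergence checks at
$n = 50{,}000$ — sizes chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick to run. The
experiment script evaluates 100 rounds of 10-fold CV on the 795-record
training part, matching the protocol's stated repetition count.

## Known limitations

* The calibration matches first moments only; no uncertainty (standard
  errors, confidence intervals) accompanies $Q_n$ or $g$, and none is
  claimed by the protocol it implements.
* Phase-2 independence ignores confounding between factors; with
  correlated covariates the $g$ are marginal, not adjusted, effects.
* The generator's independence assumption means synthetic performance
  figures should not be read as estimates of performance on real cohorts.
* Only the binary sentinel-node positivity probability is modelled — no
  survival, treatment-benefit or positive-node-count outputs.
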
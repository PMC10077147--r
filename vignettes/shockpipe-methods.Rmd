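---
title: "shockpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shockpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cardiogenic shock (CS) complicates 5–10% of acute coronary syndrome (ACS)
admissions and carries mortality approaching 50%.  A classifier that flags
high-risk ACS patients at first contact — before shock develops — would let
clinicians escalate monitoring or mechanical support pre-emptively.  Coded
intensive-care EHR data can support such a model, but only after a
substantial pre-processing effort: cohorts must be assembled from ICD-9
codes, the same vital sign must be merged from half a dozen charting item
codes, units standardised, data-entry slips repaired, and — above all —
missing data imputed credibly, because the variables most predictive of
shock (arterial pressure, oxygen flow) are also among the most incompletely
charted.

`shockpipe` implements that pipeline end to end, and ships a synthetic
cohort generator so every stage is testable without access to any
credentialed clinical database.

## The synthetic world

`default_variable_specs()` encodes the nine model variables (heart rate,
respiratory rate, SpO2, glucose, systolic blood pressure, age, O2 flow,
sex, ECG class of the coronary syndrome, chronic-heart-failure history)
plus two imputation-support variables (heart rhythm, body temperature) with
per-class parameters taken from published per-group summary statistics of
an intensive-care ACS cohort: class 0 (no CS) e.g. heart rate 82.1 ± 16.3
bpm, class 1 (CS) 94.1 ± 18.9 bpm; categorical variables carry per-class
level frequencies (the printed CS-class ECG frequencies sum to 100.01% and
are renormalised).  The default cohort is 2,130 controls and 123 patients,
the roughly 1:17 imbalance of the reference cohort.  Missingness is
masked per variable at the published per-variable rates (0% for the
admission-coded variables up to 30.7% for arterial systolic pressure),
missing completely at random: the mask never looks at values or labels.

Design choices a user should know about:

* **Multimodality.** O2 flow is generated as a two-component Gaussian
  mixture (low-flow nasal cannula ~2.5 lpm vs. high-flow mask ~10–12 lpm
  regimes, with the high-flow component more prevalent in the shock class).
  The reference material shows this bimodality but does not parameterise
  it; the mixture weights/means/SDs here are package choices, fixed once,
  chosen so that a mean-filling imputer visibly destroys the distribution
  while a donor-based one preserves it.
* **Correlation.** Cross-variable dependence is induced by a Gaussian
  copula on a user-supplied matrix (default: independence).  The supplied
  matrix parameterises the latent normals; the implied Spearman correlation
  is \((6/\pi)\arcsin(\rho/2)\), within 0.018 of \(\rho\) everywhere.  No
  published inter-variable correlation estimates exist for the reference
  cohort, so the default identity is a stand-in, not a claim.
* **Events.** The event emitter writes each variable under one of several
  source item codes (timestamps uniform in a synthetic stay window, only
  their order matters), plus ICD-9 diagnosis/procedure rows per class, so
  that cohorting, clustering, first-recorded selection and unit conversion
  are exercised end to end; `clean_events()` reconstructs the generator's
  matrix cell for cell.
* **Seeds.** One master seed; every stochastic stage derives a labelled
  child seed (`child_seed()`), so runs are byte-reproducible and adding a
  stage never shifts another stage's draws.

A green test on this world establishes that the *machinery* is correct at
the stated effect sizes and missingness rates.  It does not establish
clinical performance: the synthetic marginals are (mixtures of) Gaussians
with none of the skew, censoring, digit-preference or informative-charting
structure of real EHR data, and the default copula is independence.

## Cleaning rules

First-recorded selection takes, per stay and per variable cluster, the
value of the earliest event among the cluster's source codes after per-code
unit conversion (°F→°C is exact arithmetic); timestamp ties break
lexicographically by item code.  Outlier handling is deliberately a single
deterministic rule: a value outside the variable's *hard range* whose tenth
lands inside the *plausible range* is divided by 10 (the classic 375 °C
chart slip); a value outside the hard range that cannot be repaired is
deleted.  Shipped hard ranges are generous (±8 SD of the reference
marginals) because they exist to catch order-of-magnitude entry errors, not
to trim genuine tails; only the temperature bounds follow a documented
clinical precedent.  All repairs and deletions are logged one line per
cell.

## Imputation engines

* **Chained equations (MICE) with PMM.**  Variables with missing cells are
  visited in ascending-missingness order; each target is modelled from all
  other (currently completed) variables by a gradient-boosted tree
  ensemble; continuous targets are imputed by predictive mean matching with
  5 donor candidates (the imputed value is always an actually observed
  value, so empirical support — including bimodality — is preserved);
  categorical targets are drawn from the predicted class distribution.
  Sweeps stop when the mean absolute change of imputed continuous cells (on
  the z-scored scale) falls below `tol` (default 1e-3) or after `max_iter`
  (default 5) sweeps.  `m` independent chains (default 10) give `m`
  completed datasets; chain stochasticity comes from the random initial
  fill and the PMM/categorical draws.
* **KNN.** Distances are Euclidean on z-scored continuous coordinates over
  the variables both rows observe, scaled by \(\sqrt{p_{total}/p_{shared}}\)
  (the standard incomplete-data convention — rows sharing few coordinates
  are *not* spuriously close; a draft design note had the fraction
  inverted, which would do the opposite).  Continuous cells take the donor
  mean, categorical cells the donor mode with ties by level order.
* **SoftImpute.** Iterates \(Z \leftarrow \mathrm{SVT}_\lambda(P_{obs}(X) +
  P_{miss}(Z))\); the fixed point solves \(\min \tfrac12\|P_{obs}(X-M)\|_F^2
  + \lambda\|M\|_*\).  `lambda = "auto"` selects the shrinkage by held-out
  observed-entry error over a geometric grid under the top singular value.
* **IterativeSVD.** Rank-`r` truncated-SVD reconstruction with observed
  entries re-clamped each sweep (default r = 10).

Both completion methods run on the `encode_mixed()` representation:
continuous columns z-scored on observed cells, categoricals one-hot with
argmax decoding, observed cells restored exactly on output.  The in-package
gradient-boosted learner (see below) also backs the MICE conditionals; its
capacity there is deliberately light (30 trees, 15 leaves, 64 bins).

### Numerical choices worth recording

* *λ-continuation.*  A proximal SVT step moves the iterate only O(λ) per
  sweep, so small shrinkage values are approached through a warm-started
  geometric ladder from just below the top singular value; the objective is
  monotone non-increasing at each fixed λ (tested).
* *What λ→0 actually recovers.*  The λ→0 limit is the **minimum nuclear
  norm** completion, which is not always the minimum *rank* completion.
  For the 2×2 fixture `[[1,2],[2,?]]` the rank-1 closure is 4 (nuclear norm
  5) but the nuclear-norm minimiser is 1 (norm 4): SoftImpute correctly
  converges to 1, while rank-constrained IterativeSVD (r = 1) recovers 4.
  One inherited acceptance assertion expects SoftImpute to return 4; it is
  left failing on purpose, with the convex-oracle behaviour pinned by a
  passing unit test, because "fixing" it would mean shipping a wrong
  SoftImpute.
* *Standardisation vs. low-rank structure.*  Column centering adds a
  rank-one term, so exact low-rank recovery tests run with
  `standardize = FALSE`; mixed clinical data uses the default `TRUE`.
* *Tie-breaks.*  All nearest-neighbour machinery (ENN votes, SMOTE
  neighbours, PMM donor pools, KNN donors) resolves distance ties by index
  or level order, making every engine bit-reproducible and matching the
  brute-force oracles exhaustively on small instances.

## Imputation quality evaluation

For every variable with initially missing cells and every completed
dataset, the values imputed *at the initially missing positions* are
compared with the initially observed values by a two-sample
Kolmogorov–Smirnov test (asymptotic p at effective size \(nm/(n+m)\); a
permutation mode exists for small samples).  All variable × dataset
p-values are then jointly corrected by the Benjamini–Yekutieli step-up
procedure (valid under arbitrary dependence, harmonic factor
\(c(m)=\sum_{i\le m} 1/i\)) and annotated with stars (adjusted p < 0.05 /
0.01 / 0.001).  Categorical variables are tested on integer level codes
ordered by observed frequency — KS on categoricals is a pragmatic surrogate
rather than a calibrated test, and the log records the caveat per variable.
Correcting across the full grid (not per dataset) is the package default; a
flag switches to per-dataset families.  Per-variable method selection takes
the lowest mean KS statistic, MICE chains averaged, ties preferring MICE
then the fixed engine order.

## Class rebalancing and the classifier

SMOTE over-samples the minority (shock) class to parity by convex
interpolation toward one of the 5 nearest minority neighbours (categorical
columns copied from the seed row); a single Edited-Nearest-Neighbours pass
(k = 3) over the combined set then removes any row whose neighbourhood
majority disagrees with its label.  Resampling happens **inside each
training fold only** — validation folds keep the natural class ratio; the
cross-validation engine asserts, via provenance tracking of every synthetic
row's parents, that no validation row ever contributes to training
material.  This is the single most consequential validity decision in the
package: resampling before splitting leaks synthetic copies of validation
rows into training and inflates AUC.

The classifier is a gradient-boosted decision tree ensemble: 100
estimators, 31 leaves, balanced class weights, no hyperparameter tuning.
No maintained GBT package exists in the supported dependency set, so the
package ships its own histogram-based leaf-wise Newton-boosting learner
(`gbt_fit()`, Rcpp): quantile binning to ≤255 bins, best-first growth by
second-order gain \(G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) -
G^2/(H+\lambda)\), damped Newton leaf values, weighted logistic or
squared-error loss.  It is deterministic given its inputs; all CV
randomness lives in the fold shuffling and resampling streams.

Evaluation is repeated stratified K-fold cross-validation (default 5 splits
× 50 repeats) over all MICE-imputed datasets, folds shared across datasets
so comparisons are paired.  AUC is computed by the Mann–Whitney rank
identity (ties counted half), accuracy at the 0.5 probability threshold,
and aggregates are mean ± SD with a normal-approximation 95% CI over runs —
the presentation style of the reference experiment.  Bivariate screening
(chi-squared for categoricals; Welch t when both groups pass a Shapiro–Wilk
check on a deterministic ≤500-point quantile subsample, Mann–Whitney U
otherwise) and the derived shock index (heart rate / systolic pressure;
non-positive pressure gives NA) feed the feature selection narrative.

## Orchestration

`run_pipeline()` executes simulate → cohort (strict and relaxed ICD-9
selection; the relaxed union-of-diagnoses cohort is the imputation
expansion) → clean → MCAR mask → impute (default 13 datasets: 10 MICE + KNN
+ SoftImpute + IterativeSVD) → evaluate → *restriction* (back to the strict
cohort and the nine model variables plus shock index; expansion-only
subjects and imputation-support variables never reach the classifier) →
rebalance + train under repeated stratified CV.  Every artifact is plain
CSV/JSON; the manifest records a config fingerprint, all child seeds and
per-artifact content hashes, and reruns with the same config and seed
reproduce the manifest hash exactly.

## Known limitations

* Synthetic marginals are Gaussian (mixtures); real vitals are skewed,
  bounded and digit-preferenced.  SpO2 in particular can exceed 100% in the
  synthetic world.
* MCAR only, by design; no MAR/MNAR simulation or imputation.
* KS-on-categoricals is a surrogate; the level encoding matters for power.
* The in-package GBT is a minimal learner: no feature/row subsampling,
  monotonicity constraints or early stopping.
* CV accuracy at the 0.5 threshold is sensitive to the rebalancing ratio;
  the AUC is the stable headline metric.
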
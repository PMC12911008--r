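---
title: "Models and methods behind devfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind devfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

devfuse studies a question from developmental cognitive neuroscience: how
well does a preschool child's baseline resting-state functional connectivity
predict their motor and executive-function (EF) development over the
following year? Because no individual-level data from such cohorts are
openly deposited, the package pairs the full analysis machinery with a
seeded synthetic cohort generator that reproduces the statistical structure
the analysis assumes. Everything downstream — feature extraction, the fusion
classifier, the leakage-free evaluation protocol, importance and trajectory
analyses — is therefore testable end to end.

## The synthetic cohort

`cohort_spec()` fixes the study conditions: 256 children aged 3–6 at
baseline, assessed at 0, 6 and 12 months; retention 88.7% and 78.9% at the
follow-ups; total wave-level missingness 11.3% and 21.1% (at these defaults
all of it is attrition — the printed missing rates equal the rounded dropout
fractions); scan state is natural sleep below 60 months of age and quiet
wakefulness with a video above, which adds a configured increment to
visual-network connectivity (the scan-state confound); mean framewise
displacement falls from 0.32 mm in 3-year-olds to 0.21 mm in 6-year-olds.
Behavioral norms per year-of-age group (MABC-2-like percentiles, spans,
go/no-go accuracy, switch costs, scaled scores) are the generator's
calibration table; measures the underlying battery does not enumerate are
synthetic stand-ins and flagged as such in `default_behavior_norms()`.

A single standard-normal latent factor eta per child couples brain and
behavior. It shifts the sensorimotor-related connectivity blocks (loading
0.06 correlation units per SD at `effect_size = 1`) and loads on the
12-month behavioral change (z-loading 1.2 at effect 1, plus a small 0.25
baseline loading), so baseline connectivity is genuinely predictive of
subsequent change and the strength of that coupling is a single dial. The
defaults (`effect_size = 0.5` on both arms) are a moderate regime; the
calibration experiments below use the dial's endpoints.

Two structural choices keep the null condition honest, i.e. make the
12-month outcome *unpredictable by construction* when `effect_size = 0`:

* **Random-walk occasion noise.** If test-retest noise were i.i.d. across
  waves, change scores would be negatively correlated with baseline scores
  (regression to the mean) and any classifier consuming baseline scores
  would beat chance at zero effect. Occasion noise is therefore a
  participant-level random walk: the change increments are independent of
  the baseline draw.
* **Baseline-anchored norms and trends.** Norm means differ across age
  groups by different amounts (and cap at the oldest group), so a
  current-age lookup would make expected change a function of age, which is
  itself recoverable from baseline features. Scores instead grow from the
  baseline age-group anchor at a constant within-person rate derived from
  the age-3 to age-6 norm span — in raw units for motor percentiles (whose
  change score is taken in percentile points) and in z units for cognitive
  measures (whose change enters through the standardized composite).
  Connectivity age trends are likewise anchored at baseline age, with
  configured wave deltas (+0.07 sensorimotor, +0.05 visual, −0.04
  control–default, +0.01 limbic per 12 months) carrying the longitudinal
  change, so `network_change_contrasts()` recovers a configured delta
  exactly. Baseline cross-sections match the norm table per age group;
  follow-up cross-sections approximate it.

Residual non-idealities are documented rather than hidden: clamping
percentiles to [0, 100] shifts subgroup means by an analytically computable
amount (the tests use the truncated-normal expectation as the oracle) and
leaves a small age–change dependence near the bounds. Attrition is monotone
and driven by a logistic score on observed auxiliaries only (SES, motion,
scan state) plus independent noise — missing at random by construction —
with counts forced to `round(retention * n)` so the printed 227/202 flow is
exact. Item-level masking beyond dropout uses a logistic mechanism on the
same auxiliaries with the intercept calibrated to the requested wave-level
rate. What the generator does **not** emulate: physiological fMRI noise,
scanner drift, spatial structure within regions, multi-factor brain–behavior
coupling, or non-monotone (intermittent) missingness; passing tests say
nothing about those aspects of real data.

## Features

Connectivity matrices are Pearson correlations (`fc_matrix()`; constant
regions are a hard error because silent NaNs poison every downstream graph
metric; Fisher z is available behind a flag but off by default, matching the
raw-correlation pipeline). `vectorize_upper()` fixes a row-major
upper-triangle order shared with `upper_index_map()`, so block-level feature
groups stay consistent; at 360 regions the vector has 64,620 entries, at the
evaluation scale of 90 regions 4,005. `qc_filter()` implements the motion
rule (exclude if mean FD > 0.5 mm or more than 20% of volumes above
threshold; boundaries pass).

The 12 graph metrics are computed on proportionally thresholded graphs
(default density 0.15, the package's choice where no rule is stated;
proportional thresholds equalize density across subjects). Distances are
1/weight shortest paths (compiled Floyd–Warshall); clustering is the Onnela
weighted form; the partition comes from seeded Louvain; participation and
within-module degree follow the standard nodal formulas. Three metrics are
z-scored against degree-preserving rewired nulls with weights shuffled onto
the rewired edges (default 50 nulls; the experiment grids use 10, the
documented floor), and small-worldness is (C/C_null)/(L/L_null). Two listed
features are underdetermined by their names alone and the package fixes
them explicitly: the scalar "within-module degree" is the mean within-module
strength fraction (its ensemble z-score is the companion feature), and the
"hub score" is the fraction of nodes with nodal within-module-degree z above
1. Every metric is checked against exhaustive brute-force oracles on graphs
of up to 8 nodes, including the null-based ones on the stored ensembles.

## Composites and outcomes

The EF composite is the reliability-weighted mean of the working-memory,
inhibitory-control and cognitive-flexibility domain z-scores, rescaled so
the defining sample has mean exactly 100 and SD exactly 15. Domain weights
default to the mean task alpha per domain (0.80/0.83/0.775); sample-estimated
alphas via `cronbach_alpha()` are supported. Both the six-measure modeling
composite and the narrower three-subtest variant are exposed. Outcomes are
median splits of the observed 12-month change (total motor percentile; EF
composite points): strictly-above-median is class 1, ties go to class 0 (a
fixed rule so labeling is deterministic), and participants lacking an
observed change are absent — labels are never imputed.

## The fusion classifier

The classifier has four channels: the connectivity vector passes through a
1-D convolution (128 filters, kernel 7, stride 1 by default), ReLU,
non-overlapping max-pooling (size 4) and a dense layer of 64 units; the 12
graph metrics through dense 32→16; the 16 motor and 12 cognitive scores
through dense 32 each. Channel outputs are concatenated and fused by a
128→64→32 MLP with dropout (default 0.3) and a single logit. Training is
binary cross-entropy with Adam (lr 0.001), batch 32, at most 100 epochs,
early stopping on validation loss with patience 10 and best-weights restore.
The implementation is a compact, fully seeded neural network in R matrix
operations with the convolution kernels compiled; identical data, config and
seed give identical histories and predictions. After restoring the best
weights the output bias is recalibrated on the *training* fold so the mean
predicted probability equals the training base rate — early-stopped networks
can leave the logit off-center, which costs accuracy at the fixed 0.5
threshold; the correction uses training data only.

Ablations `connectivity_only` (connectivity + graph channels) and
`behavioral_only` (motor + cognitive) consume only their own channels,
verified by zeroing the unused ones. Where the feature counts printed for
individual outcome rows elsewhere are irreconcilable with the stated
64,620 + 12 + 16 + 12 inventory, the inventory wins; and one model is
trained per outcome.

## Leakage-free evaluation

`stratified_kfold()` builds 5 folds stratified by age band (3–4 vs 5–6
years) crossed with outcome class; `holdout_split()` provides the separate
70/15/15 split (179/38/39 at n = 256). Within each training fold,
`fold_preprocess()` runs chained stochastic regression imputation (Bayesian
posterior draws per chain, m = 20 by default) with the complete auxiliaries
(age, sex, SES, mean FD, scan state) plus the low-dimensional feature
columns as predictors, and z-score scaling — all fit strictly on the
training fold; test-fold missing values are filled from train-fitted draws
and test features scaled with train parameters. Label columns are
structurally un-imputable (hard error). The guard is asserted literally in
the tests: perturbing the test fold leaves every train-fitted parameter
bit-identical. Each fold trains on `m_train` completed datasets (default 5;
the experiment grids use 1 — with complete baseline features the completed
sets coincide) with an inner stratified 15% early-stopping split, pools
predicted probabilities by averaging, and reports accuracy, rank-based AUC
and F1 overall and per age stratum. Cross-validation is the primary
evaluation; the holdout split is provided separately because fold-wise
mean ± SD is the headline quantity.

## Importance and trajectories

Grouped permutation importance jointly row-permutes a group's columns in the
held-out fold (100 repeats by default), reporting the mean accuracy drop in
percentage points, a 5-point substantive-contribution flag, and Kendall's W
(with tie correction) of the group rankings across folds. Accuracy is the
degraded metric; AUC is available behind a flag. Default groups are the four
channels plus each connectivity network block.

Growth slopes are per-participant OLS slopes of score on months — exactly
reproducible, reducing to the two-point difference quotient with two waves —
rather than mixed-model BLUPs; an optional shrinkage was considered and
rejected to keep the subgroup rule auditable. Accelerated development
requires both the motor and the EF slope to exceed the sample mean by more
than 1 SD simultaneously (slower: both below −1 SD); under a bivariate
normal slope distribution the expected accelerated fraction is the upper
orthant probability, which the tests check against numerical integration
across slope correlations 0, 0.5 and 1. Partial correlations residualize
both variables on the covariate design (intercept; dummies for categorical
covariates) and use the Fisher z interval with the n − k − 3 adjustment.
The trajectory model comparison fits Gaussian random-intercept models by
maximum likelihood (so AICs are comparable across fixed-effect structures):
a natural cubic spline of age with df 3 and interior knots at 48 and 60
months versus a linear age term, both with sex, SES (two dummies, low as
reference), mean FD and scan state; the spline is preferred only when the
AIC difference exceeds 10. Calibration: on linear-truth simulations the rule
picks the linear model in at least 90% of 20 seeded runs, and a strong
inverted-U (amplitude 0.15 correlation units, vertex at 57 months) flips it
to the spline.

## Problem sizes and numerical choices

The packaged experiments run at what a single desktop CPU handles in
minutes, chosen once and stated here: 90 regions (the 360-region geometry is
supported; its upper triangle is 64,620 features), 10-null ensembles inside
experiment grids, cohorts of 200 (null calibration) and 300 (signal
recovery) with 10 seeds each, and a reduced architecture for the experiment
grids (`model_config_desk()`: 32 filters, stride 7, pool 4, lr 0.003,
dropout 0.2, 60 epochs with patience 12) — stride and filter count are
explicitly configurable model dimensions, and the full-scale defaults remain
those of `model_config()`. Other numerical choices: thresholding ties break
by fixed index order; disconnected graphs define path length over finite
pairs with a warning; zero null SD yields a z of 0 with a warning;
degenerate zero-variance slope sets classify everyone typical with a
warning; the logistic missingness intercept is solved by `uniroot` on
[−30, 30]; indefinite correlation targets for time-series sampling are
repaired to the nearest positive-definite matrix with a warning.

## Known limitations

The generator's latent coupling is a single scalar factor; real
brain–behavior covariance is richer, and the multimodal-over-unimodal
ordering the tests verify is a property of this construction, not evidence
about real cohorts. Follow-up-wave cross-sections only approximate the norm
table because of baseline anchoring. The spline comparison uses a random
intercept only (no random slopes), matching the subgroup rule's need for
exact reproducibility rather than maximal realism. Percentile clamping
leaves a small residual age–change dependence near the scale bounds.
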
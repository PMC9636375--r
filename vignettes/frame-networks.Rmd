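---
title: "Frame networks: rank-stable functional connections and their group alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame networks: rank-stable functional connections and their group alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(framenet)
```

## The model

A functional connectome study gives, per subject, an N x N matrix of
Fisher-z transformed Pearson correlations between regional time series.
Most network analyses threshold these matrices, and their conclusions
shift with the threshold. The frame-network construct asks a
threshold-robust question instead: *which connections occupy the same
position in the strength ordering in (almost) every subject?*

Within each subject, all E = N(N-1)/2 signed edge strengths are ranked
ascending (weakest = 1, strongest = E; ties share the average rank, so a
rank vector always sums to E(E+1)/2). For edge *e* with rank mean
$\mu_e$ and sample SD $\sigma_e$ across the S subjects of a cohort, the
coefficient of variation $CV_e = \sigma_e / \mu_e$ is the stability
statistic, and the frame network is the $k$ edges of smallest CV, with

$$k = \mathrm{round}(N^2 f / 2), \qquad f = 0.01 \text{ by default.}$$

The count uses the full-matrix convention (the $N^2$ cells of the square
matrix, halved), not the number of unique pairs: at N = 90 and f = 1%
this gives round(40.5) = 41, whereas 4005 x 1% would give 40. Halves
round up; a 1e-9 guard keeps binary floating-point representation of
fractions like 0.05 from flipping a half case.

Three choices deserve emphasis:

- **Ranks are taken on signed strengths.** Strongly negative edges rank
  lowest. The CV criterion does not itself force selected edges to be
  strong — it selects *stable* ranks — but because $\mu_e$ enters the
  denominator, an edge pinned near the top of the ordering has a far
  smaller CV than one pinned near the bottom, so in practice frame edges
  are stable *and* strong. `rank_sd_diagnostic()` exposes rather than
  assumes this: in control-like cohorts the correlation between mean
  rank and rank SD is strongly negative (about -0.7 in the bundled
  simulations).
- **The CV uses the sample SD** (denominator S-1). Selection is
  insensitive to this choice, since population and sample SD differ by a
  factor common to all edges; a test asserts this invariance via scale
  invariance of the selection.
- **Ties at the CV cutoff** are broken by larger mean rank (stronger
  edge first), then edge index — deterministic, so cohorts that are
  subject permutations of one another give identical networks, and
  threshold sweeps are exactly nested.

## What the simulator emulates

`cohort_spec()` defines a latent-factor generative model. Each planted
edge (a, b) with loading $\lambda \in (0,1)$ contributes a shared
unit-variance latent series weighted by $\sqrt{\lambda}$ to both
regions, on top of independent Gaussian noise with SD $\sigma$ (default
0.4). When each region carries one factor, the population correlation of
a planted pair is $\lambda/(\lambda + \sigma^2)$ — monotone in
$\lambda$, and the implied covariance is positive semidefinite by
construction (no ad-hoc PSD projection). `population_correlation()`
returns this closed form and serves as the analytic oracle in the tests.

Defaults emulate a medicated case-control study: 71 controls vs 60
patients, 90 AAL regions, 140 timepoints. All 45 homotopic (X_L, X_R)
pairs are planted with loadings spread over 0.5-0.9 — the strong,
symmetric interhemispheric backbone — and, when patients are requested,
a left-frontal clique (dorsolateral superior frontal, middle frontal,
medial superior frontal, precentral, left side) is planted weak
($\lambda = 0.15$) and strengthened fourfold in patients while eight
homotopic edges are weakened (multiplier 0.7), reproducing the
left-lateralized concentration and the bidirectional strength
alterations the analysis is designed to detect. Covariates follow the
published demographics (controls aged 36.23 +/- 11.63, motion 0.15 +/-
0.08; patients 38.77 +/- 16.28, motion 0.20 +/- 0.11; sex and
handedness as categorical draws), with patient motion deliberately
larger so covariate adjustment is exercised. Between-subject
variability enters as truncated-normal jitter (SD 0.05 by default) on
each loading. The published record does not state the across-subject
variance of edge strengths, so the jitter default is a free parameter
of this package, chosen to keep planted edges stable-and-strong without
making them deterministic; it is not fitted to any reported number.

When a symptom edge is designated (default: the homotopic supplementary
motor area pair, target correlation 0.36 with a PANSS-negative-style
score), scores are built from the *realized* Fisher-z strength of that
edge: the Gaussian noise term is orthogonalized against the realized
strengths and unit-scaled, so the pre-rounding sample correlation equals
the target exactly; integer rounding to the 7-49 item-sum range then
perturbs it by a few hundredths.

What the simulator does **not** emulate: hemodynamics, scanner noise
spectra, autocorrelated BOLD fluctuations, motion artifacts, or any of
the volume-level preprocessing chain (slice timing through band-pass
filtering) — inputs to this package are cleaned regional time series or
connectivity matrices by contract. Passing tests therefore demonstrate
correctness of the statistics on data satisfying the model's
assumptions, not robustness to fMRI artifacts.

## Numerical choices and degenerate inputs

- Correlations are clipped to |r| <= 1 - 1e-7 before arctanh, keeping
  Fisher z finite for collinear (degenerate synthetic) inputs; the
  matrix diagonal is stored as 0 and never ranked or selected.
- A zero-variance region is an error naming the region; a zero-variance
  symptom score is skipped with a warning and reported as undefined
  rather than silently dropped.
- Edges with zero rank SD (CV = 0) are legal and sort first; they arise
  only in degenerate inputs such as identical subjects.
- `edge_stability()` refuses single-subject cohorts (an SD across one
  subject is not a stability estimate).
- Under the half-up convention, 0.5% of the 90 x 90 matrix selects
  round(20.25) = 20 edges; a ceiling convention would give 21. The 1%
  headline count of 41 is identical under both; the half-up choice is
  flagged as a sensitivity point for sub-1% thresholds.

## Group comparison

"Two-sample t-test with covariates" is implemented as the ordinary
least squares regression t of the group indicator —
`strength ~ intercept + group + age + sex + handedness + motion` — the
standard reading; with no covariates this is algebraically the pooled
two-sample t (asserted to 1e-6 in the tests), and a Welch variant is
exposed for the covariate-free case. The patient-minus-control
orientation is fixed so that "decreased" means weaker in patients.
Degrees of freedom are n minus the number of model columns. Categorical
covariates collapse absent levels automatically — an all-right-handed
cohort simply drops the handedness column — while a constant *numeric*
covariate is a hard error, since it signals a data problem rather than
a sampling accident.

P-values are Benjamini-Hochberg adjusted. The adjustment family is a
genuinely open choice: this package defaults to the designated edge set
for the group comparison (the edges actually tested) and to all
edge x score pairs jointly for symptom correlations, both configurable.
Calibration at the study's sample sizes (71 + 60, one-SD standardized
effects) is verified by simulation in the test suite: null cohorts flag
well under 8% of edges and planted effects are detected in over 90% of
replicates.

## Classifier

The linear SVC (LIBSVM via e1071) follows the nested design: an outer
leave-one-out loop; inside each training split, features are z-scored
with training statistics only and a stratified k-fold (default 5)
selects the cost constant from `c_grid` by mean balanced accuracy, ties
to the smallest constant; the tuned model is refit on the full training
split and the held-out subject's label and signed decision value are
recorded. Metrics pool the held-out predictions; the AUC is the
Mann-Whitney statistic of decision values (ties half-weighted), pooled
across folds. Per-feature weights $w = \sum_i \alpha_i y_i x_i$ are
averaged over the outer folds. Permutation p-values use the add-one
estimator $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$ — never
exactly zero — and every permutation reruns the entire nested
procedure, hyperparameter search included (the conservative choice).

Two defaults depart from naive practice, for measured reasons:

- **Balanced class weights** (inverse training frequency) are on by
  default. Plain leave-one-out on a balanced null cohort is
  systematically *anti*-predictive — the training majority is always
  the class opposite the held-out subject — and measured null
  accuracies averaged 0.32 (as low as 0.08) without weights, versus a
  properly chance-level 0.51 with them. Weighting also compensates the
  unequal group sizes typical of case-control designs.
- **The cost grid starts at 0.1.** With balanced weights, costs of 0.01
  and below put the weighted hinge loss on an exact knife edge in every
  leave-one-out training split (the weighted class masses tie), and the
  fitted model's predictions become floating-point accidents — observed
  as all-or-nothing null accuracies of exactly 1.0 or 0.0. Constants
  from 0.1 to 1000 cover the useful regularization range for z-scored
  connectivity features.

A deliberate-leakage contrast (standardizing on all subjects before
cross-validation) is kept in the test suite and must differ from the
per-fold standardization on small noisy cohorts.

## Design findings worth knowing

**Recovery of planted frame edges is insensitive to loading jitter.**
With 41 planted homotopic edges at S = 60 subjects, recovery at the 1%
threshold is exact for every jitter SD probed (0.02 up to 4, i.e. far
past the point where per-subject loadings are essentially uniform on
(0, 1)). The reason is structural: jittered loadings remain positive,
so planted edges never leave the upper region of the rank ordering,
while a null edge's rank is near-uniform over all 4005 positions,
putting a hard floor (~0.4) under null CVs that planted CVs never
reach. Selection degrades only when the planted-versus-null separation
itself collapses, not through rank shuffling within the stable block.
The corresponding tests assert exact recovery at low jitter and
monotone non-increase across jitter levels.

**Problem sizes in the tests and acceptance script** are chosen for
fast, deterministic simulation: calibration runs use 31-edge families
at the study's 71 + 60 sample sizes over 100-200 replicates; classifier
behavior is checked at 60 subjects with 10 features; recovery runs use
the full 90-region, 60-subject, 150-timepoint design once per jitter
level. Each is stated in the code next to its use.

## Known limitations

- The CV statistic is descriptive; no inferential theory (null
  distribution of CV) is provided or used.
- Graph metrics beyond degree and hemispheric composition (small-world,
  rich-club, modularity, formal asymmetry indices) are out of scope.
- The simulator's independence of latent factors means it cannot
  produce correlated null edges (e.g., global signal); real cohorts
  will have a less clean null CV floor.
- Printed accuracies in published reference studies computed as
  averaged fold metrics can differ from total-correct/total; this
  package defines accuracy as total correct over total and does not
  attempt to reproduce any other averaging.
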
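---
title: "Predicting a binary clinical outcome from multiomics blocks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting a binary clinical outcome from multiomics blocks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

omicboost implements a complete analysis chain for predicting a binary
clinical outcome — the motivating application is postoperative recurrence
and metastasis in a colorectal-cancer cohort — from several heterogeneous
omics blocks measured on the same patients: a small table of clinical
categories, binary somatic-mutation indicators, and two wide blocks of
log2-normalized protein and phosphosite abundances. This vignette explains
each stage's model and assumptions, the tunable parameters and their
defaults, what the synthetic cohort generator does and does not emulate,
and the design choices made where the method description left the design
genuinely open.

```{r setup}
library(omicboost)
```

## The pipeline at a glance

1. **Label completeness filter** — samples without an outcome label are
   dropped (`filter_labelled()`); a supervised model can use only labelled
   records.
2. **Feature selection** (`select_features()`) — discrete features are
   tested for association with the outcome by Fisher's exact or chi-square
   test; continuous features by the intersection of pooled-variance t,
   Mann-Whitney U and one-way ANOVA tests at level `alpha`.
3. **Dimensional reduction** (`assemble_design()`) — selected discrete
   features pass through; each continuous block's selected features are
   replaced by their first `L = 2` principal components, giving a compact
   unified design matrix.
4. **Sample-size estimation and augmentation**
   (`estimate_cohort_sample_size()`, `smote_augment()`) — a classical
   two-sample power formula decides whether the cohort is large enough;
   if not, SMOTE interpolation doubles the dataset, and the maximum
   Fisher's discriminant ratio scores the augmentation's quality.
5. **Boosted heterogeneous ensemble** (`fit_ensemble()`) — AdaBoost over
   logistic-regression, support-vector and naive-Bayes weak learners,
   fused by a logistic stacking layer.
6. **Evaluation** (`kfold_evaluate()`) — stratified K-fold
   cross-validation with accuracy, precision, sensitivity, specificity and
   F-measure, pooled ROC/AUC, and paired t tests of each baseline against
   the ensemble.

`run_pipeline()` chains the stages, fans a single master seed out to each
stage via `derive_seed()`, and writes every artifact with a hashed
manifest, so a configuration reproduces a run byte for byte. The package
is function-first: the exported functions, this vignette and the worked
example in the README are the intended interface, with YAML configuration
(`read_pipeline_config()`) for scripted runs.

## The synthetic cohort generator

Real patient multiomics data cannot ship with a package, so every stage is
exercised against `generate_cohort()`, whose defaults emulate the study
conditions the pipeline was designed for:

* 144 samples with a near-balanced outcome (70 positive / 74 negative);
  a variant with 146 samples and 2 missing labels exercises the
  completeness filter;
* two small discrete blocks — clinical (10 features, 3 informative) and
  mutation (20 features, 3 informative) — with binary codes;
* two wide continuous blocks — proteomics (600 features, 89 informative)
  and phosphoproteomics (1,000 features, 15 informative). The informative
  counts mirror the motivating study's selected-feature counts
  (3/3/89/15); the total widths are reduced from 6,408 and ~22,000 so the
  test suite stays fast, which leaves the *multiplicity* of null features
  smaller than in the real data but the per-feature testing problem
  unchanged.

Continuous informative features are Gaussian with a standardized
between-class mean shift of `effect_size` (default 1.0, a typical
magnitude for abundance differences that survive selection in omics
cohorts of this size; the two class means sit at ±half the shift with
shared variance `noise_sd = 1`). Discrete informative features are
Bernoulli with a log-odds shift of `effect_size` (default 1.5) around a
baseline carrier rate of 0.3. Non-informative features are identically
distributed in both classes, so with `effect_size = 0` the whole cohort is
exchangeable across classes — the null configuration used for calibration
tests.

The generator does **not** emulate: correlation structure among proteins
(features are independent given the class), batch or plate effects,
heavy-tailed or missing abundance values, or clinically realistic
covariate distributions (clinical codes are binary). Consequently a
passing suite shows the pipeline's logic and calibration are correct under
its own assumptions, not that the method will reach any particular
accuracy on real patient data. One visible consequence: with 89
independent informative proteomics features sharing one shift direction,
the first principal component separates the synthetic classes almost
perfectly, so cross-validated accuracies near 1 are expected on the
default cohort — far above what heterogeneous real cohorts yield.

## Feature selection

The statistical primitives are implemented from their defining formulas —
hypergeometric enumeration for Fisher's exact test, the margin-based
Pearson statistic, the pooled-variance t, the pairwise-score U with ties
counted 0.5, and the sum-of-squares ANOVA decomposition — and the test
suite verifies them against independent oracles (brute-force enumeration,
`stats::fisher.test()`, `t.test()`, `wilcox.test()`, `aov()`).

Design choices where the method was open:

* **Fisher vs chi-square.** The conventional validity rule decides per
  feature: Fisher's exact test whenever any expected cell count is below
  5, chi-square otherwise (`method = "auto"`, either test can be forced).
* **Integration of the three continuous tests.** The default rule is the
  intersection — a feature is selected only if *all three* p-values fall
  below `alpha` — the most conservative reading of "integrating" the
  tests; `"majority"` and `"any"` are available and the rule used is
  recorded in the report. The intersection of three highly correlated
  tests has size at most `alpha`, which the calibration tests confirm
  empirically on null cohorts.
* **Multiple testing.** No correction by default, matching the procedure
  the pipeline reproduces; a Benjamini–Hochberg flag (`adjust = "BH"`) is
  available for stricter use.
* **Mann-Whitney p-value.** Tie-corrected normal approximation without
  continuity correction. Only the U statistic itself feeds the published
  procedure; the approximation choice affects borderline p-values at tiny
  group sizes, which the binary-outcome use case (class sizes ~70) never
  approaches.
* **The t test is the pooled-variance form** (the form the defining
  equations give); Welch's variant is deliberately not offered as a
  default to keep the selection rule faithful.
* ANOVA is implemented for any number of groups but is applied here to
  two, where F = t² exactly — a redundancy the suite exploits as a
  cross-check rather than a reason to drop the test.

## Dimensional reduction

Each continuous block is reduced independently by PCA on its selected
features: centering only, no unit-variance scaling, because abundances are
assumed median-normalized and log2-transformed upstream (a `scale` flag
exists for other inputs). Two components per block is the default, chosen
because the leading two components of an informative block separate the
classes visibly; the resulting design matrix is, at the default
conditions, 3 clinical + 3 mutation pass-through columns plus 2 + 2
principal components — a 10-column design. (The motivating study's prose
mentions reducing to 11 features while its enumeration yields 10; the
implementation follows the enumeration.)

Numerical conventions: components are ordered by decreasing explained
variance; each loading column's largest-magnitude element is made
positive, so loadings and scores are reproducible across linear-algebra
backends; requesting more components than `min(n - 1, p)` is an error
that names the attainable range, and a block whose selection is smaller
than `L` keeps every attainable component with a warning.

## Sample-size estimation and augmentation

For each selected feature the classical two-sample requirement is

$$n = \frac{\sigma^2 (Q_1^{-1} + Q_2^{-1}) (\mu_\alpha + \mu_\beta)^2}{\delta^2}$$

with pooled SD $\sigma$, observed mean difference $\delta$, class
proportions $Q_1, Q_2$, and standard-normal quantiles
$\mu_\alpha = 1.96$ (two-sided 0.05) and $\mu_\beta = 0.8416$ (power
0.8) by default. Choices made here:

* Estimates are computed on the **selected raw features** (the Table-1
  analog), not on principal-component columns, whose trailing components
  have near-zero $\delta$ and would inflate the requirement without
  bound.
* $Q_1, Q_2$ are taken as the outcome class proportions.
* Per-feature requirements aggregate to a per-block and overall
  requirement by the **maximum** (only the most demanding feature
  guarantees every feature is adequately powered); the mean is available.
* A zero mean difference flags an infinite requirement; if every feature
  is flagged the dataset is insufficient regardless of augmentation and
  the aggregation errors out.

When the available count falls short, `smote_augment()` generates `m`
synthetic rows per original (default `m = 1`, doubling the dataset):
among the row's `k = 5` same-label Euclidean nearest neighbours, `m` are
drawn without replacement and each synthetic row is
$x_{new} = x_i + u\,(x_{ij} - x_i)$ with a *single* uniform $u$ per row
(one scalar gap multiplier, matching the defining update; a
per-coordinate variant is deliberately not the default). Labels are
inherited, so class balance is preserved exactly and every coordinate
lies within the seed–neighbour segment. Distances are Euclidean on the
unscaled design columns — the design's pass-through codes and PC scores
are already on comparable scales — and discrete pass-through columns are
snapped back to the nearest original category after interpolation.
Augmentation here enlarges the *whole* near-balanced dataset; it is not
minority-class rebalancing.

Quality is scored by the maximum Fisher's discriminant ratio
$F_1 = \max_i (\mu_{1i} - \mu_{2i})^2 / (\sigma_{1i}^2 + \sigma_{2i}^2)$,
computed before and after augmentation with per-class sample standard
deviations (an `"se"` variant exists because the source description's
wording is ambiguous between deviations and errors). Interpolation pulls
within-class points toward their class interior, so SMOTE raises $F_1$,
while the Gaussian-jitter baseline `noise_augment()` (default scale 0.2
SD per feature — a modest jitter; scale 0 duplicates the data) inflates
within-class variance and lowers it. The suite confirms this ordering on
the default cohort across seeds, mirroring the qualitative finding that
interpolation-based augmentation preserves class geometry better than
noise.

## The boosted stacked ensemble

Each of the three weak-learner families is boosted independently by
discrete AdaBoost: uniform initial weights $D_1(i) = 1/n$, per round the
weighted error $\epsilon_t$, the round weight
$\alpha_t = \tfrac12 \ln((1-\epsilon_t)/\epsilon_t)$, and the
renormalized update $D_{t+1}(i) \propto D_t(i) e^{\mp\alpha_t}$. The
boosted score of family $m$ is $H_{mT}(x) = \sum_t \alpha_t h_t(x)$ with
weak predictions mapped to $\{-1, +1\}$ (the 0/1 labels are mapped to
signs internally and back at the stacking layer). A hard ±1 vote is used
rather than a probability score, because the weighted-sum form
presupposes sign votes; a probability variant can be built via a custom
learner but is not a default.

Numerical and procedural choices:

* **T = 10 rounds** per family by default — small and conventional; on
  strongly separable data boosting stops earlier (see below).
* $\epsilon_t$ is clipped to $[10^{-10}, 1 - 10^{-10}]$, so a perfect
  weak learner receives the finite ceiling weight
  $\tfrac12\ln((1-10^{-10})/10^{-10}) \approx 11.5$. After a perfect
  round the weight update leaves $D$ unchanged, so boosting records the
  round and stops — continuing would repeat it verbatim.
* A round with $\epsilon_t \ge 0.5$ (no better than chance under the
  current weights) triggers one re-initialization to uniform weights; a
  second such round stops boosting early.
* **Sample weights**: weighted fitting where the family supports it —
  logistic regression via weighted IRLS, Gaussian naive Bayes via
  weighted class moments (hand-written, since per-sample weights are
  required) — and seeded weighted resampling for the RBF support vector
  machine, which has no per-sample weight interface. The mode is recorded
  on each learner spec.
* **Stacking**: the three boosted margin scores feed a logistic combiner
  $\mathrm{logit}\,H(x) = c_0 + \sum_m c_m H_{mT}(x)$. Scores can come
  from the training data itself (`"in_sample"`, faithful to a workflow
  that fits the combiner without a split) or from internal stratified
  5-fold out-of-fold prediction (`"out_of_fold"`, the default, avoiding
  optimistic combiner weights). On the easy default cohort all members
  are often perfect and collinear; aliased or constant score columns
  receive zero combiner weight with a warning, which resolves the
  degenerate case gracefully.

## Evaluation

Stratified K-fold cross-validation (K = 5 by default; the fold count was
unstated in the motivating procedure and 5 is the field convention) with
seeded fold assignment. Held-out scoring always uses original rows only —
synthetic rows carry provenance flags and are structurally excluded from
test folds. Three augmentation policies:

* `"none"`;
* `"train_folds_only"` (default): SMOTE runs inside each fold on training
  originals only — leakage-safe;
* `"whole_dataset_first"`: SMOTE runs once before splitting and synthetic
  rows join every training set — reproducing the augment-then-validate
  ordering of the motivating workflow; its optimism (test-fold
  information reaching training through interpolated rows) is the reason
  it is not the default, and the report records which policy was used.

Metrics come from exact confusion counts; zero-denominator ratios are
reported as 0 with an `undefined` flag rather than NaN. ROC curves are
built by a threshold sweep in which tied scores cross together, and AUC
by the trapezoid rule; with the 0.5-per-tie convention this equals
U/(n·m), an identity the suite asserts across modules to 1e-10. Paired
two-sided t tests on per-fold accuracies compare each baseline against
the ensemble; when all folds tie exactly (common on the easy synthetic
cohort) the paired test is undefined and reported as NA. An off-the-shelf
gradient-boosted-tree comparator (`"gdbt"`, via xgboost) can be added to
the model list; its internals are outside this package's scope.

## Problem sizes used by the tests

The suite runs the full chain on the default 144-sample cohort (1,630
features across four blocks) for 20 seeds in its end-to-end checks, the
exhaustive Fisher-oracle comparison over all 135,750 contingency tables
with n ≤ 40, and the Fisher-ratio population-limit check at n = 10,000 —
sizes chosen so the whole suite completes in a few minutes on one core
while still averaging stochastic checks over enough replicates to be
stable.

## Known limitations

* Independence of features within a synthetic block makes the default
  cohort easier than real multiomics data; accuracy comparisons between
  models on it are compressed toward the ceiling.
* The SMOTE neighbour search is exact (full distance matrix), fine for
  hundreds of samples, quadratic beyond.
* Ensemble serialization stores structure (coefficients, per-round
  weights and errors) as JSON, not the fitted weak-learner objects;
  refitting from the recorded configuration is the supported way to
  reproduce a model.
* The ANOVA, U and t selection tests share the two-class location-shift
  target; the intersection rule therefore behaves almost like the single
  most conservative test rather than genuinely independent evidence.
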
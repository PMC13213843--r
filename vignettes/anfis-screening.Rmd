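---
title: "Methods: neuro-fuzzy screening for early developmental disability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuro-fuzzy screening for early developmental disability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the generative
model behind the synthetic cohorts, the classifier and its training
protocol, the numerical and design choices that were genuinely open, and
what the package's tests do and do not establish about real clinical data.

## The screening problem

Developmental disability screening in children aged 1–6 years rests on four
standardized assessment domains — cognitive, behavioral, motor, and social
interaction — each scored 0–100 (higher is better), together with age, sex,
and a binary family history of developmental conditions. The classifier's
job is binary: flag children for comprehensive multidisciplinary evaluation.
Because such flags carry clinical weight, the model must expose its
reasoning — which domains fired which linguistic categories (Low / Medium /
High), and how confident the call is — rather than only emit a probability.

## The synthetic cohort generator

Raw clinical records of this kind are not freely distributable, so the
package ships a generator whose defaults encode the cohort structure the
analysis assumes. These defaults **are** the study conditions; they are set
once and not tuned:

* Group sizes: 4,311 typically developing and 689 diagnosed children
  (prevalence 13.8%), as fixed counts rather than Bernoulli draws, so
  prevalence-dependent statistics carry no group-size noise. A
  total-plus-prevalence parameterization is also accepted, resolving the
  diagnosed count by nearest-integer rounding.
* Domain scores: independent truncated normals on [0, 100] within each
  group. Group means/SDs default to cognitive 60.86 ± 14.51 vs
  51.58 ± 17.09, behavioral 55.82 ± 9.38 vs 49.64 ± 11.21, motor
  51.08 ± 7.79 vs 45.08 ± 8.00, social 51.20 ± 11.66 vs 42.13 ± 11.19
  (typical vs diagnosed).
* Family history: group-conditional Bernoulli with rates 0.450 (typical)
  and 0.856 (diagnosed); sex likewise with p(female) 0.517 and 0.489.
* Age: discrete uniform on {1, …, 6}. Its mean 3.5 and SD 1.708 match the
  reported cohort age profile (3.49 ± 1.72), which is why the uniform was
  adopted over an unidentifiable alternative.

Gaussian-per-group marginals are the minimal model consistent with the
group means, SDs and the observed correlation structure; higher moments
(skewness, kurtosis) of real assessment scores are unconstrained by the
available summary statistics, and the generator makes no attempt to model
them. Within-group independence of the four domains is justified by the
near-zero inter-domain correlations reported for the real cohort (−0.02 to
0.03); a correlated generator would need information that does not exist in
the published summaries.

Two consequences matter for interpreting test results. First, the
group-conditional structure *implies* the headline cohort-level statistics
rather than imposing them: the overall cognitive mean (≈ 59.58), overall
family-history rate (≈ 50.6%), the moderate negative point-biserial
correlations of each domain with diagnosis (social ≈ −0.26), and the
family-history phi (≈ 0.28) all emerge from the group parameters, which is
what the acceptance checks verify. Second, the generator emulates marginal
and first-order association structure only — no site effects across centers,
no longitudinal drift, no informative missingness, no rater noise. A model
that performs well here has been shown to learn the intended signal, not to
be clinically validated.

### Truncated-normal sampling

Scores are sampled by inverse-CDF conditioning: a uniform draw on
[Φ((low−μ)/σ), Φ((high−μ)/σ)] pushed through the normal quantile function.
This is genuine conditioning (no point mass at 0 or 100, unlike clipping)
and consumes exactly one uniform per variate, so the RNG stream — and hence
byte-for-byte reproducibility from the seed — does not depend on an
acceptance rate, as rejection sampling would. For the default parameters the
truncation bias is below 0.3 score units; the tests bound it against
numerically integrated truncated-normal means.

An optional per-cell missingness rate (default 0) exercises the
missing-data policy; it is uniform at random, which is the weakest and most
testable assumption.

## Preprocessing

* **Sex encoding**: male → 0, female → 1. The direction is arbitrary and
  documented; sex is not among the model features, so it affects only
  bookkeeping. Matching is case-sensitive with an explicit case-folding
  toggle, so silent label drift in input files is caught rather than
  absorbed.
* **Missing-data policy**: rows missing more than 10% of the six key
  developmental variables (four domain scores, age, family history) are
  dropped; remaining gaps are mean-imputed from the kept rows. The policy is
  idempotent.
* **Scaling**: min-max to [0, 1], fitted on the training partition only
  (standard anti-leakage practice; the split-fit order is asserted by a
  test), with out-of-range evaluation values clamped to [0, 1].
* **Splitting**: stratified 80/20 with per-class test counts rounded
  half-away-from-zero and the total reconciled by adjusting the majority
  class by at most one.

## Feature engineering

The model consumes exactly 11 features: the 4 raw domains, 4 age-adjusted
ratios (score/age), 2 cross-domain ratios, and the weighted composite risk.
This decomposition (4 + 4 + 2 + 1) is the only one consistent with the
constructions described for the screening feature set and with its
importance ranking, which lists precisely these entries; age, sex and raw
family history are not direct inputs — family history enters only through
the composite-risk multiplier.

Ratios and the composite risk are computed on the raw 0–100 scale and only
then is the full 11-column matrix min-max normalized; the worked clinical
case (cognitive/social ratio 1.04, composite risk 33.81 for scores
64.45/74.14/68.35/61.20) is reproducible only in that order, which pins the
convention. The score inversion inside the risk is (100 − score), confirmed
by the same worked value. The family-history multiplier for positive history
is not pinned by any published value; the default is 1.25 (a 25% risk
uplift, consistent in direction and rough magnitude with the 85.6% vs 45.0%
history rates), configurable, and equal to 1 for negative history — the
worked case reproduces with multiplier 1, implying negative history there.

Mutual information against the label is estimated with 10 equal-width bins
and the plug-in estimator in nats; features above 0.01 are flagged as
retained. The screen is advisory: the model trains on all 11 features, and
the screen's role is post-hoc simplification evidence. At n = 5,000 the
estimator's bias for an independent feature, roughly
(bins − 1)/(2n) ≈ 0.001 nats, sits well below the threshold.

## ANFIS architecture and training

First-order Sugeno inference was chosen over zero-order: the consequents
"apply linear functions" of the inputs, which is the standard ANFIS form.
Three Gaussian membership functions per feature share one bank across the 8
rules (grid-partition style). The open architectural question — shared bank
vs per-rule Gaussian parameters — is resolved in favor of sharing, which
matches a per-feature Low/Medium/High reading and keeps the membership
functions interpretable as feature-level categories after training.

* **Membership initialization**: centers at 0, 0.5, 1 on the normalized
  range; width 0.25, giving substantial overlap so gradients flow between
  neighboring categories from the first epoch.
* **Rule initialization**: the published architecture fixes 8 rules but not
  which 8 of the 3¹¹ antecedent combinations. The package clusters the
  training features with k-means (seeded) into 8 groups and maps each
  centroid coordinate to its nearest membership-function center; duplicate
  antecedents are perturbed to the second-nearest category on the
  highest-variance feature. A seeded random initializer is the fallback for
  degenerate inputs.
* **Consequent initialization**: zero slopes; intercepts from N(0, 0.1²),
  seeded, so rules are not born identical (an all-identical start makes the
  normalized-firing gradients cancel).
* **Training**: end-to-end Adam (learning rate 0.01, β₁ = 0.9, β₂ = 0.999)
  on mean binary cross-entropy, batch size 32, up to 100 epochs, 20%
  stratified validation hold-out, early stopping at patience 10,
  best-validation-epoch weights restored. The classic hybrid
  least-squares/backprop ANFIS scheme is intentionally not implemented; the
  end-to-end gradient route matches the differentiable-graph training the
  architecture was designed around. Gradients are analytic and are verified
  against central finite differences at relative 1e-4 in the tests.
* **Class imbalance**: no reweighting, threshold fixed at 0.5, with ties at
  exactly 0.5 predicted negative (a screening-conservative, deterministic
  convention). At 13.8% prevalence this trades sensitivity for specificity;
  the evaluation module reports both so the trade is visible rather than
  hidden.

### Numerical safeguards

* Per-feature memberships are floored at ε = 10⁻¹² and the 11-way product
  is computed as a log-space sum, so a case far from every rule still fires
  (ε¹¹ is representable in double precision as exp(Σ log)) and
  normalization never divides by zero.
* Widths are clamped to σ ≥ 0.01 after every Adam step; an unconstrained
  width can collapse to zero around an isolated training point and poison
  the loss with infinities.
* Gradients through a floored membership are exactly zero, keeping the
  analytic gradient consistent with the forward computation (and the
  finite-difference check honest).
* Predicted probabilities are clamped to [1e-12, 1 − 1e-12] inside the loss
  only, never in the reported predictions.

## Evaluation

Confusion metrics follow the textbook definitions with zero-denominator
cases reported as `NA` plus a warning, never silently as 0. AUC is the
mid-rank Mann–Whitney statistic (ties ½), which equals the trapezoidal area
under the empirical ROC; the tests verify it against exhaustive pairwise
concordance and against an independent library implementation.

Cross-validation is stratified k-fold (default 5) with a fresh model per
fold. Fold summaries report the sample SD across folds **and** the
normal-approximation 95% CI (mean ± 1.96·SD/√k). These are deliberately kept
separate because published fold tables in this area sometimes print a CI
half-width in the "± SD" slot — e.g. fold accuracies of 91.5, 86.8, 89.0,
88.4, 90.3 have sample SD 1.8 but a 95% CI half-width near 3.4 — and the
package reports both so no such ambiguity arises in its own output.

Perturbation importance zeroes one normalized feature at a time (zero being
the feature's observed minimum under min-max scaling) and records the
accuracy drop with the model held fixed. Tier cutoffs (Dominant ≥ 0.005,
High ≥ 0.0025, Moderate ≥ 0.001, else Low) discretize the contribution
scores on the scale where published rankings of this feature set place
their tier boundaries.

## Clinical reporting

Confidence is |p − 0.5| / 0.5; tiers are Low (≤ 0.5), Medium (0.5, 0.8],
High (> 0.8) — the boundary 0.8 is assigned to Medium, reading the published
stratification's "High (> 0.8)" as exclusive. Per-domain linguistic labels
take the argmax membership of the normalized raw score; when the top two
memberships differ by less than 0.15, a blended label ("Medium-High") is
returned — the blend rule is this package's own device for communicating
borderline category membership, with the 0.15 gap chosen so that a tie
blends and a clear winner (membership ratio above roughly 1.2 near the
crossover) does not. Recommendations come from a fixed six-entry template
table (2 predictions × 3 tiers); free-text generation is out of scope.

## Problem sizes and reproducibility

The test suite exercises the full 5,000-child cohort for generator fidelity
and one end-to-end training run; unit tests of the training loop use
cohorts of a few hundred children and toy separable sets, which is ample to
pin the contracts (determinism, early stopping, gradient correctness)
without burning compute on repetition. Every stochastic step — generation,
splitting, fold assignment, k-means, intercept draws, minibatch order — is
governed by explicit integer seeds, and identical seeds reproduce cohort
files byte-for-byte and training histories exactly. Model artifacts are
JSON with 17-significant-digit numeric encoding, which round-trips IEEE
doubles exactly, so a reloaded model reproduces its predictions bit-for-bit.

## Known limitations

* Synthetic validation only: the generator reproduces marginal and
  first-order association structure, so test performance here bounds
  nothing about real-world accuracy. The separation achievable under these
  group-conditional marginals is materially below what a real-data study
  can report on a favorable held-out partition.
* The fixed 0.5 threshold is miscalibrated for a 13.8%-prevalence screening
  task if sensitivity is the priority; threshold tuning and cost-sensitive
  training are deliberately out of scope.
* Binary output: the heterogeneous spectrum of developmental conditions is
  collapsed to one label.
* Eight rules with a shared membership bank is an interpretability-first
  configuration; raising the rule count improves fit at the cost of the
  transparent rule table that motivates the approach.
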
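---
title: "Multimodal connectomes, network-based statistics and structure-function coupling: models and choices"
author: "netcouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal connectomes and structure-function coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, the tunable parameters and why their defaults are
what they are, the places where the methodology is genuinely open and which
branch we took, and what the synthetic validation does and does not
demonstrate about real neuroimaging data.

## 1. The analysis chain

A study analyzed with this package has, per subject, two regional data
channels on a shared atlas of R regions assigned to eight intrinsic
networks (SN, LN, VN, SMN, FPN, DMN, DAN, SVAN):

1. a T × R matrix of regional time series (functional channel), and
2. per-region samples of grey-matter voxel values (structural channel).

The pipeline turns each channel into an R × R connectome, localizes group
differences with the network-based statistic, correlates the two
connectomes at five scales ("SC–FC coupling"), tests the coupling features
with permutation tests, and feeds the significant ones to a
cross-validated linear SVM.

## 2. Functional connectome

`pearson_fc()` correlates every pair of regional time series and converts
each r to a two-sided p-value by the exact transform
`t = r sqrt((T-2)/(1-r^2))` on T − 2 degrees of freedom.
`fdr_threshold()` applies Benjamini–Hochberg over the R(R−1)/2 unique
edges at q = 0.05 and zeroes non-surviving edges, keeping the signed r of
survivors.

Choices worth making explicit:

* **BH step-up is "the" FDR here.** Where a method description says only
  "FDR-corrected", the Benjamini–Hochberg step-up procedure is the default
  meaning in neuroimaging; `stats::p.adjust(method = "BH")` implements it
  and a brute-force enumeration of the step-up rule guards it in the tests.
* **Per subject, not pooled.** Each subject's matrix is thresholded on its
  own p-values. Pooling all subjects' edges into one FDR family would be a
  defensible alternative; it is not implemented because the per-subject
  matrix is the unit every later stage consumes.
* **Signed survivors.** Negative correlations that survive are kept with
  their sign; taking absolute values would silently change both the NBS
  contrasts and the coupling correlations.
* **No Fisher z, no covariate regression.** The pipeline starts from
  regional summaries; upstream preprocessing is out of its scope.

## 3. Grey-matter structural connectome

For one subject, `build_sc()`:

1. pools all regional values to fix one evaluation grid: the pooled range
   padded by 3 pooled-Silverman bandwidths on each side, `grid_size = 128`
   points (configurable);
2. estimates each region's Gaussian-kernel density with Silverman's
   rule-of-thumb bandwidth (`stats::bw.nrd0`) and renormalizes it on the
   grid into a discrete probability mass (`estimate_density()`);
3. computes, for every pair of regions, the Jensen–Shannon divergence in
   base 2 — `JSD(p,q) = ½KL(p‖m) + ½KL(q‖m)`, `m = (p+q)/2`, with
   `0·log 0 = 0` — and the similarity `JSS = 1 − sqrt(JSD)`.

Why these choices:

* **Base-2 logarithms** bound JSD by 1, so the similarity lands in [0, 1]
  with no extra normalization.
* **"Distance" means sqrt(JSD).** The square root of the base-2 JSD is a
  metric bounded by 1, and `1 − distance` is the natural similarity on
  [0, 1]. Because the literature also uses `1 − JSD` directly, that
  variant is exposed (`variant = "one_minus_jsd"`); both respect the
  bounds, and all downstream stages are agnostic to the choice.
* **One shared grid per subject** (not per pair) makes all R masses
  directly comparable and the matrix internally consistent; the grid
  travels with the data, so adding a constant to every value of a subject
  leaves the matrix unchanged (a tested invariant).
* **Silverman bandwidth** is a pragmatic default for unimodal,
  roughly-Gaussian regional value distributions; with multimodal real
  data a different bandwidth rule would be worth revisiting. A degenerate
  (constant) sample falls back to a bandwidth of 1e-3 of the grid span.

The discretized similarity is validated against adaptive quadrature of the
closed-form JSD of known normal densities: on a 4096-point grid the two
agree to about 1e-13, far inside the 0.01 working tolerance.

## 4. Network-based statistic

`nbs_test()` follows the classical component-extent recipe: pooled-variance
two-sample t per edge, a one-tailed primary threshold
(`qt(1 - primary_p, nA + nB - 2)`, strict inequality), connected components
of the suprathreshold graph (via igraph, cross-checked against a
flood-fill oracle), and the permutation null of the **maximal** component
extent under group-label shuffling. Corrected
`p = (1 + #{perm max extent ≥ observed extent}) / (1 + n_perm)` — the +1
estimator is never exactly zero and is unbiased against optional stopping.

Decisions:

* **One-tailed per direction.** Increased and decreased subnetworks are
  separate scientific claims, so each direction runs as its own one-tailed
  contrast at `primary_p`; a two-tailed |t| mode exists for users who want
  a single omnibus family.
* **Extent, not intensity.** Component size is its edge count, matching
  how such components are reported (nodes/edges); an intensity statistic
  (sum of suprathreshold t) would weight strong focal effects more but is
  not what the reported numbers mean.
* **Ties at the threshold are excluded** (strict `>`): a permutation that
  reproduces the critical t exactly does not create an edge.
* **Zero pooled variance** at an edge (e.g. both groups all-zero after FDR
  thresholding) defines t = 0 rather than NaN.

On the calibration experiment in the acceptance suite (20 regions, 10
subjects per group): with only 190 edges, a 0.001 primary threshold leaves
well under one suprathreshold edge per null draw, so the max-extent null
is almost all zeros and the test, while valid, has essentially no
resolution — its empirical family-wise error sits near zero. The
calibration therefore runs at a primary p of 0.01, where suprathreshold
edges actually occur and the measured FWER (~0.015–0.045 across seed
families) sits inside the nominal band while staying conservative, as the
discreteness of extents and the +1 estimator imply. The pipeline default
for real-scale analyses remains 0.001.

## 5. Structure–function coupling

`coupling_profile()` computes five scales per subject:

| scale | edge set | value |
|---|---|---|
| whole-brain | strictly positive SC edges | cor(Gaussianized SC, FC) |
| global-network | within-network edges of one network | cor(SC, FC) |
| node | one region's row, self excluded | cor(SC row, FC row) |
| within-network | node's partners in its own network | cor |
| between-network | node's partners outside its network | cor |

* **Gaussianization** (`gaussianize()`) is the rank-based inverse-normal
  transform with the Blom offset, `qnorm((rank − 0.375)/(n + 0.25))`,
  average ranks on ties. It is applied only at the whole-brain scale,
  where the procedure it implements prescribes it; sub-scales correlate
  raw values by default, with `gaussianize_sc = TRUE` available
  everywhere. A consequence worth knowing: the whole-brain coupling is
  invariant to any strictly increasing transform of the SC values (tested
  to 1e-12).
* **FC zeros participate.** Edges zeroed by FDR thresholding enter the
  coupling correlations with value 0 — the correlation is against "the FC
  matrix", not a masked version. Masking would confound coupling with FC
  sparsity.
* **"Nonzero SC values" is applied as written** (strict positivity); with
  Jensen–Shannon similarities the excluded set is generically empty, so
  the clause is harmless but faithful.
* **Missing, never zero.** Scales that are undefined (a 2-region network,
  a constant row) return NA and are excluded from group statistics, never
  imputed; the screen reports them as untestable features.
* Pearson is the correlation everywhere ("correlation coefficient" read
  in its default sense); `method = "spearman"` is available.

Every scale is checked against literal edge-list loop implementations to
1e-12.

## 6. Group inference

`permutation_mean_diff_test()` uses the difference of group means as its
statistic — the simplest exchangeable statistic, monotone in t when group
sizes are fixed — with two-sided p
`(1 + #{|perm| ≥ |obs|})/(1 + n_perm)`. When `choose(n, nA) ≤ 10000` the
null is enumerated exhaustively (p = count/total, the identity keeping it
positive). `coupling_group_screen()` applies it feature-wise; significance
is p < 0.05 **uncorrected** by default — mirroring the workflow this
package implements, which reports uncorrected screens and flags that as a
limitation — with Benjamini–Hochberg as an opt-in (`adjust = "BH"`).

`welch_t_from_summary()` reconstructs two-sample t tests from printed
means/SDs/ns. Welch's unequal-variance form is the default because a
demographics table with one tight and one dispersed group (SDs 2.89 vs
12.09) is only reproduced by Welch (t = −0.24; the pooled form gives
−0.28). `chi_square_2x2()` is the Pearson chi-square without continuity
correction, the convention under which a 17/8 vs 9/9 gender table gives
1.42.

## 7. Classification

`loocv_classify()` holds out one subject per fold, standardizes features
**on the training subjects only** (a deliberate-leak regression test shows
whole-sample standardization changes predictions), fits a linear-kernel
SVM (C = 1, `e1071::svm`), and predicts the held-out subject; sensitivity
is the proportion of patients correctly predicted, specificity the
proportion of controls. The three reported metrics are, by construction,
exactly recomputable from the per-subject predictions — an identity the
tests enforce, since printed metric triplets that cannot be reconciled
with any confusion matrix at the stated group sizes are a known
reporting hazard in this literature.

`select_features()` mirrors the classical select-then-classify workflow:
features significant in the group screen on the **full sample** form the
feature space. That leaks selection information into the cross-validation
and flatters the accuracy; the `nested` hook of `loocv_classify()` redoes
selection inside every training fold and is the honest alternative (the
stage-5 analysis script reports both). C = 1 and within-fold z-scoring are
unstated-by-the-method defaults. Linear discriminant and bagged-tree
backends exist as robustness checks with library defaults.

`permutation_test_classifier()` permutes labels before the entire LOOCV
and uses `(1 + #{null accuracy ≥ observed})/(1 + n_perm)`.

## 8. The synthetic cohort generator

`simulate_cohort()` provides ground truth for validation. Its model:

* **Regional gradient.** Regions carry a smooth location gradient μ over
  [0, 3]; region r's grey-matter values are N(μ_r, 0.35²), so nearby
  regions have overlapping distributions and high Jensen–Shannon
  similarity. Networks are contiguous on the gradient, giving the SC
  matrix a realistic community structure.
* **Functional covariance.** Time series are zero-mean multivariate
  normal. The correlation matrix combines within-network blocks at
  ρ_w = 0.5 over a between-network baseline ρ_b = 0.1, plus an alignment
  term `0.3·exp(−Δμ²/(2·0.6²))` tying functional similarity to structural
  proximity — this is what makes baseline SC–FC coupling positive (~0.7
  at the node scale) — plus subject-specific symmetric edge noise with
  sd 0.1, and is projected to the nearest symmetric positive-definite
  correlation matrix by eigenvalue clipping at 1e-6 (block constructions
  are routinely indefinite).
* **Planted effects.** FC block effects add a signed shift to the named
  network-pair block of the patient covariance. Structural pair effects
  shift the μ of two networks' regions apart or together in patients,
  moving their pairwise similarity down or up. Coupling effects scale the
  subject-specific edge noise on the rows of a network's regions (×3 for
  "weaker", ×0.2 for "stronger"): more noise degrades the agreement
  between that subject's FC rows and the SC-aligned structure without
  changing the expected FC, less noise tightens it. This noise-scaling
  construction is the package's own device — no generative coupling model
  is prescribed anywhere — and it has a known side effect: heavy edge
  noise followed by positive-definite projection slightly shrinks mean
  correlations of the affected rows, so strong "weaker" effects can leak
  a small mean-FC signature.
* **Determinism.** Per-subject seeds derive from the master seed by a
  fixed affine rule below 2³¹, so cohorts are bit-reproducible and any
  subject can be re-simulated alone.

Defaults (18 patients / 25 controls, T = 230, 40 regions, 100 voxels per
region) mirror the study shape this pipeline targets at a desk-scale
region count; all are configurable. A full 246-region whole-brain atlas is
supported via a named size map.

**What passing the synthetic suites does and does not show.** The cohorts
are Gaussian, stationary, autocorrelation-free and unimodal per region; no
hemodynamics, no motion, no registration error, no atrophy gradients along
anatomy. Recovery of planted effects demonstrates the statistical
machinery is correct and calibrated — it does not demonstrate sensitivity
to real ALS effects, whose sizes no desk simulation can certify. The
planted shift magnitudes are free parameters chosen to be comfortably
detectable at the simulated sample sizes, not estimates of disease effect
sizes.

## 9. Validation problem sizes

The acceptance suite runs: FWER calibration on 200 null cohorts (20
regions, 10 vs 10, 500 permutations, T = 60); recovery of a planted
DMN–FPN block shift (+0.3) on 50 cohorts of 20 vs 20 at T = 230; JSS
oracle on 100 random normal pairs at grid 4096; coupling oracles on
20-region matrices; coupling-sign recovery on 50 cohorts of 12 vs 12 at
T = 150 with 80 voxels per region; 500 null draws for permutation
calibration; and a full screen-select-classify pass on an 18 vs 25 cohort.
These sizes are the package's chosen compromise between Monte-Carlo error
and a test suite that runs in minutes on one CPU.

## 10. Known limitations

* Kernel density with a global Silverman bandwidth underfits multimodal
  regional distributions.
* The NBS implementation tests plain two-sample differences; covariate
  adjustment at the edge level (GLM residualization) is out of scope.
* Uncorrected coupling screens inflate the selected-feature count; the BH
  switch exists but changes the meaning of downstream feature selection.
* Select-then-classify without nesting overstates accuracy; always compare
  with the nested variant before believing a number.
* The generator's coupling manipulation operates through covariance noise,
  one of many mechanisms that could produce decoupling in real brains.
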
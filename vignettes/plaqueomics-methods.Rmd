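---
title: "Methods: radiomic texture analysis of coronary plaque cross sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic texture analysis of coronary plaque cross sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Advanced coronary atherosclerotic lesions (fibroatheromas and thin-cap
fibroatheromas) carry a materially higher risk of rupture than early lesions,
but on contrast-enhanced CT angiography they are hard to tell apart: expert
visual pattern reading (homogeneous / heterogeneous / napkin-ring sign) is
moderately accurate and poorly reproducible, and histogram summaries of the
segmented plaque — the area of voxels below 30 HU, or the mean HU — ignore
*where* the low-attenuation tissue sits. The hypothesis this package
operationalizes is that the spatial arrangement of tissue components, captured
by a large panel of radiomic texture and geometry descriptors fed to machine
learning, discriminates better than either reading.

`plaqueomics` implements that pipeline end to end: NRRD image/mask I/O, a
1919-parameter radiomic engine, the histogram baselines, a randomized-search
model-building procedure over eight classifier families scored by
cross-validated AUC, DeLong confidence intervals and paired ROC comparisons,
and a synthetic plaque phantom generator that makes every stage testable
without clinical data.

## The feature taxonomy

Each lesion is a masked voxel set: HU values, integer grid coordinates,
physical spacing. Feature extraction is deterministic and produces exactly
1919 uniquely named parameters in four blocks:

* **First-order (44)** — statistics of the marginal HU distribution: mean,
  median, mode, dispersion and shape moments, fourteen percentiles (linear
  interpolation between order statistics), trimmed and winsorized means,
  midhinge, and entropy/uniformity of equal-width bin occupancies at
  B = 16, 32, 64. Degenerate lesions (single voxel, constant value) return 0
  for otherwise-undefined dispersion terms so the cohort matrix stays finite;
  those columns are zero-variance and are removed by preprocessing anyway.
* **Gray-level co-occurrence (6 × 114 = 684)** — on each of six discretized
  images (equal-width and equal-probability binning at 16/32/64 gray levels),
  symmetric mask-restricted co-occurrence matrices are built for the 13
  unique 3D directions at distances 1, 2, 3. Nineteen Haralick-family
  statistics per matrix are aggregated over directions by mean and by range,
  giving 19 × 2 × 3 = 114 per image. Logs are base 2 with 0·log 0 := 0; the
  two informational measures of correlation use the exact identities
  HXY1 = HXY2 = HX + HY, which hold for any joint distribution whose
  marginals sum to one. Maximum probability stands in for the numerically
  fragile maximal-correlation statistic.
* **Gray-level run length (6 × 11 = 66)** — maximal runs of equal gray level
  along the 13 directions (a segmentation gap terminates a run), summarized
  by the eleven classic Galloway/Chu/Dasarathy–Holder statistics and
  averaged over directions, matching the co-occurrence mean convention.
* **Geometry (5 + 2·(16+32+64)·5 = 1125)** — on the original mask: exposed
  -face surface area under anisotropic spacing, volume, and fractal
  box-counting, information, and correlation dimensions; then the same five
  quantities (surface, surface ratio to the total, three dimensions) for
  every gray level of every discretized image. Empty gray levels yield
  zeros; sub-mask surfaces may exceed the total surface for fragmented
  levels, so ratios are only bounded below.

Fractal dimensions are least-squares slopes over box grids of side
1, 2, 4, 8, 16 voxels anchored at the set's bounding-box origin; the three
scaling curves (log2 occupied boxes, occupancy entropy, log2 occupancy second
moment) are regressed against log2 of the scale with sign conventions that
make all three non-negative for ordinary sets. Fixed power-of-two scales and
a fixed anchor keep the features deterministic; offset averaging would be
smoother but data-dependent in cost. A full 16³ cube recovers dimension 3
exactly, a 16×16×1 slab dimension 2.

Equal-probability binning assigns the k-th smallest of n voxels to bin
floor((k−1)·B/n)+1, ties broken by stable coordinate order, so bin counts
differ by at most one and the assignment is reproducible. Lesions smaller
than B simply leave some bins empty; all downstream features tolerate empty
gray levels.

## The phantom generator

No clinical images ship with the package; the generator emulates what the
analysis assumes about contrast-enhanced coronary plaque cross sections:

* an annular or crescent vessel-wall mask, 3 slices thick, outer radius
  5–12 voxels, at 0.4 × 0.4 × 0.6 mm spacing — masked sets of roughly
  10²–10³ voxels;
* fibrous wall tissue at N(90, 25) HU with a mild smooth in-plane gradient;
* in advanced lesions, a spatially contiguous necrotic/lipid core at
  N(20, 15) HU occupying 15–40% of the mask, ring-shaped with probability
  0.3 (the napkin-ring analog);
* visual-pattern labels assigned by the generative rule (no core →
  homogeneous, blob core → heterogeneous, ring core → napkin-ring) and
  flipped to a random other category with probability 0.25 to emulate
  imperfect reading;
* 445 lesions per cohort at 30% advanced prevalence (round-half-up, so
  exactly 134 advanced).

The HU means and dispersions are plausible for contrast-enhanced plaque
tissue and were chosen once so the 30 HU low-attenuation threshold is
meaningful; no quantitative lesion HU distributions were available to fit.

The **matched-marginal design** is the key testing device: each early lesion
is built by drawing an advanced-style value field on its own mask and then
spatially permuting the values. The HU multiset is preserved exactly, so the
two classes have identical per-lesion histograms by construction and differ
*only* in spatial arrangement. Any first-order or histogram-based reading is
uninformative on such a cohort (AUC ≈ 0.5), while texture and geometry
features retain signal — which is precisely the ordering the study design is
meant to exhibit.

Reproducibility: lesion i's private RNG stream seed is the i-th integer
drawn from a Mersenne-Twister generator seeded with the cohort seed. This is
prefix-stable (lesion i is identical whether generated alone or inside any
cohort) and carries no arithmetic structure in the index; an earlier affine
seed map (a·seed + b·index mod p) produced measurable cross-correlations
between the cohort-level class assignment and lesion content and was
replaced.

What the phantoms do **not** model: CT physics (beam hardening, partial
volume, noise texture of iterative reconstruction), lumen contrast,
calcified components, or anatomically realistic wall remodeling. Passing
tests on phantoms therefore demonstrates the correctness and the qualitative
behavior of the pipeline, not clinical performance.

## Model building

The training table is processed per configuration as: (a) drop zero-variance
columns; (b) robust scaling, (x − median)/IQR per column, with
linear-interpolation quartiles (zero-IQR columns are dropped); (c) univariate
two-sample ANOVA F-tests (for two classes, F = t²) with a false-positive-rate
filter p < α_FPR followed by a Bonferroni family-wise filter
p < α_FWER/m, where m counts the features entering that second step;
(d) PCA keeping the smallest number of components whose cumulative explained
variance reaches the sampled target. Every statistic is estimated on
training rows only and the frozen transform is applied unchanged to held-out
data; a configuration whose selection step retains nothing is flagged and
scored 0.5.

Randomized search draws, per configuration: α_FPR and α_FWER log-uniform on
[1e-4, 0.5], the PCA variance fraction uniform on [0.80, 0.999], and family
hyperparameters from these grids:

| family | hyperparameters |
|---|---|
| logistic regression | ridge C log-uniform [1e-3, 1e3] (glmnet, λ = 1/(C·n)) |
| K-nearest neighbors | k ∈ 1..50 |
| random forest | trees ∈ 50..500, depth ∈ 2..20 (as a node-count cap) |
| least angle regression | nonzero-coefficient budget ∈ 1..50 along the lasso path; the continuous linear prediction is the classifier score |
| Gaussian naive Bayes | variance smoothing log-uniform [1e-12, 1e-6] × max feature variance |
| Gaussian process | RBF length scale log-uniform [0.1, 100] |
| decision tree | depth ∈ 1..20, minimum leaf ∈ 1..20 |
| neural network | one hidden layer of 8/16/32/64 units, L2 decay log-uniform [1e-6, 1e-1], 200-iteration cap |

The neural-network family is restricted to a single hidden layer: at a few
hundred tabular training rows, deeper fully connected stacks only add
unidentifiable parameters, and the installed single-hidden-layer
implementation (`nnet`) is the standard R choice. The Gaussian naive Bayes
with additive variance smoothing is implemented in-package because no
installed implementation exposes that hyperparameter.

Configurations are scored by stratified five-fold cross-validated AUC of the
continuous model output. Stratification guarantees both classes in every
fold at 30% prevalence; the fold assignment is derived from the search seed
once and reused for every configuration, so scores are comparable across
configurations and the scaling statistics and univariate p values — which
depend only on the fold split — are computed once per fold rather than per
configuration (an exact, not approximate, reuse). Ties in the winner are
broken by evaluation order, making the search fully deterministic given the
seed. The winning configuration is refitted on the complete training set
before validation scoring.

## Evaluation

AUC is the tie-aware Mann–Whitney statistic; its variance comes from
DeLong's placement values (per-positive and per-negative), the 95% CI is
AUC ± 1.96·SE clipped to [0, 1], and paired curves are compared with the
DeLong z test using the placement covariance. Scores that are monotone
transforms of each other give a zero-variance difference; that case is
flagged degenerate rather than assigned a p value. The in-package
implementation is cross-checked against an independent reference (pROC) in
the test suite.

The low-attenuation baseline counts voxels strictly below 30 HU times the
in-plane pixel area, divided by the number of occupied z layers — a mean
per-cross-section area, reflecting that the measurement is defined per cross
section while the phantoms are thin slabs. Baselines and the 3-category
visual pattern are turned into validation scores by univariate logistic
models fitted on training rows; under complete separation the fitted
probability is a monotone transform of the predictor, so the score falls
back to the predictor's rank and the AUC is unchanged.

## Numerical and testing choices

* Problem sizes: the end-to-end experiment in the acceptance material uses
  the full 445-lesion cohort with 100 random configurations per family
  (800 evaluated pipelines, 4000 fold fits); oracle-equivalence tests run
  on 100 random small lesions against brute-force double-loop
  implementations at 1e-10.
* The pooled-histogram balance check for the matched-marginal design uses
  the two-sample KS statistic referred to a *lesion-level permutation null*:
  pooled voxels are correlated within lesions, so the iid KS p value
  over-rejects for any clustered generator even when the class laws are
  identical.
* The paired DeLong test's type-I error is verified by simulation (2000
  independent null pairs) to sit in [0.03, 0.07] at α = 0.05, and the
  false-positive-rate filter is verified to pass ≈ α of pure-noise features.
* Co-occurrence matrices with no valid voxel pair (possible for large
  distances on thin masks) are flagged empty and contribute zeros.

## Limitations

Phantom realism is the main one: no scanner physics, no calcium, no lumen,
and HU distributions chosen by plausibility rather than fitted to data. The
matched-marginal cohort makes histogram baselines uninformative *by
construction*, which is the point of the design but also means the absolute
AUC values reported on phantoms say nothing about clinical discrimination.
The feature catalog fixes choices (the 44-statistic first-order set, the
19 × {mean, range} × 3-distance co-occurrence composition, volume as the
fifth whole-mask geometry parameter) that reproduce the documented counts
exactly but are one of several defensible compositions; the full dictionary
is exported via `feature_names()` so downstream work can audit every column.
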
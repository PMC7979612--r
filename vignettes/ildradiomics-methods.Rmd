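---
title: "Methods: a radiomics staging pipeline for SSc-ILD chest CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a radiomics staging pipeline for SSc-ILD chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Interstitial lung disease (ILD) is the leading cause of death in systemic
sclerosis (SSc). Disease severity is commonly summarized by the GAP staging
system — a composite of Gender, Age and Physiology (FVC and DLCO percent
predicted) — while chest HRCT is read visually for fibrosis patterns
(ground-glass opacity, reticulation, honeycombing). The question this
pipeline operationalizes: can quantitative texture descriptors of the lung
parenchyma (radiomics) predict a patient's GAP stage better than visual
scoring does?

`ildradiomics` implements the full analysis as tested, reusable code:

1. lung masking by HU window and isotropic resampling,
2. a 1116-entry feature engine (shape, first-order intensity, GLCM, NGTDM,
   GLRLM, GLSZM, coiflet stationary-wavelet sub-bands),
3. MWMOTE minority oversampling to balance the heavily skewed GAP1/GAP2
   classes,
4. Boruta all-relevant selection, correlation clustering and Gini
   representatives,
5. logistic models compared by AIC with bootstrapped ROC and stratified
   cross-validation,
6. the clinical comparators: GAP points/stage, the six-lobe coarseness
   score, and the 20% fibrosis-extent rule.

Because no patient CTs ship with the package, a first-class synthetic
module generates lung phantoms and cohorts with the study's statistical
structure; every stage is exercised end to end on those.

## Image preprocessing

Lungs are segmented by an HU window, by default −950 to −150 HU, followed
by retention of the largest 26-connected component. The component filter
stands in for the manual corrections of a semi-automatic workflow: it
removes windowed voxels that are not part of the main lung body (noise
specks, hilar vessel gaps). Volumes and masks are then resampled to 2 mm
isotropic voxels — trilinear interpolation for HU, nearest-neighbour for
the mask so it stays binary. Whether masking precedes resampling is
ambiguous in a semi-automatic workflow; this pipeline masks first and
resamples both, and a test verifies the two orders agree to within
nearest-neighbour tolerance on phantoms.

Gray levels are discretized with a fixed bin *width* (10 or 35 HU),
anchored at −950 HU, i.e. `level = floor((HU + 950)/width) + 1`. The
fixed-width reading (rather than a fixed bin count) follows from the units
attached to the bin sizes; anchoring at the window's lower edge makes
levels comparable across patients. Wavelet bands are not on the HU scale,
so band discretization anchors at the band's own in-mask minimum with the
same width of 35.

## The feature registry

The registry (`feature_registry()`) is an ordered data frame of 1116
definitions; the extractor refuses unknown formula ids and returns exactly
one finite value per entry. The printed class subtotals — 4 shape, 19
intensity, 105 texture, 976 wavelet — do not sum to 1116 by themselves;
the registry resolves the remainder as 12 designated co-occurrence
features re-evaluated at bin width 10 (suffix `.b10`):
contrast, correlation, homogenity, homogenity_n, jointEntropy and
jointEnergy, in both averaged and merged (`M_`) aggregation. Each of the
eight wavelet bands carries 122 features (17 intensity — all but
minimum/maximum, which are uninformative after high-pass filtering — plus
the 105 texture features), giving 8 × 122 = 976. Since the registry is
data, alternative resolutions are configurable without touching the
extractor.

Naming conventions (kept compatible with the study's printed feature
names): prefix `M_` marks merged-direction aggregation, suffix `_n` a
normalized variant, suffix `.XYZ` a wavelet band, and the spelling
`homogenity` is kept verbatim. `homogenity`/`homogenity_n` carry the
inverse-difference formulas and `jointEnergy` the angular second moment
`sum(p^2)`; listing homogeneity, inverse difference, ASM and joint energy
as four distinct formulas would double-count two identities and break the
26-per-aggregation GLCM count.

The 16-entry size-zone set includes both the zone-size variance `sizeVar`
(probability-weighted variance of zone sizes) and `sizeVar_n`
(`sizeVar / mean(size)^2`, a squared coefficient of variation); to keep
the set at 16 with both variants, zone entropy is not included. This is a
package convention, documented here because size-zone feature lists vary
across the literature.

### Texture matrices

* **GLCM** — co-occurrences at Chebyshev distance 1 along the 13 unique 3D
  directions, symmetric. `averaged` computes the 26 statistics per
  direction and averages; `merged` sums counts first.
* **NGTDM** — Amadasun–King statistics on 26-neighborhoods restricted to
  the mask. The contrast feature is the `neighContrast` of the results
  tables.
* **GLRLM** — maximal collinear same-level runs per direction; mask gaps
  break runs. Merged run percentage uses `13 * Np` because every voxel is
  scanned 13 times.
* **GLSZM** — zones are 26-connected equal-level components.

Degenerate-value conventions keep every feature finite: correlation with a
zero marginal variance returns 0, coarseness of a flat region is capped at
`1/eps` with `eps = 1e-12`, a single-voxel mask yields all NGTDM features
0, skewness/kurtosis/CoV return 0 at zero variance, and the maximal
correlation coefficient of a single-level matrix is 1. Every matrix
feature is verified against an independent loop-based oracle on randomized
small volumes in the test suite.

### Intensity and shape

The 19 first-order features include a box-counting fractal dimension: the
in-mask values are binarized above their median, boxes of edge 1, 2, 4, 8
voxels are counted over the bounding box, and the dimension is the
least-squares slope of `log N(s)` against `log(1/s)`. The estimator
(binarization rule, box sizes) is fixed here for reproducibility; a filled
solid scores about 3, a voxel plane about 2, and an empty binarization
(constant input) returns 0.

Surface area uses a coarea estimator: the binary mask is Gaussian-smoothed
(sigma 1.2 voxels, radius-3 kernel, zero-padded border) and the integral
of the gradient magnitude approximates the surface integral. Counting
exposed voxel faces systematically overestimates oblique surfaces (a
digitized sphere comes out at 1.5 times its true area, pushing sphericity
to 0.67); the coarea estimate restores sphericity near 1 for spheres.
Sphericity is `pi^(1/3) (6V)^(2/3) / A` and the maximum 3D diameter is the
largest pairwise distance between boundary-voxel centers.

### Wavelet bands

One-level stationary (undecimated) separable transform with the coiflet-1
filter pair; band names give the per-axis filters in (x, y, z) order,
`LLL` … `HHH`. No subsampling means every band is congruent with the
input, so the lung mask applies unchanged. Boundary handling is periodic
by default, which makes the two-channel bank an exact tight frame (band
energies sum to 8× the input energy — a machine-precision test) and
handles axes shorter than the filter; reflection padding is available.

## Synthetic data

### Phantoms

`generate_volume()` renders a single right-lung ellipsoid (the study
segmented the right lung to avoid cardiac motion) of
`Normal(−850, 40)` HU parenchyma inside a soft-tissue body, clipped to
[−1000, 100]. Fibrosis covers a connected subpleural region — the lung
voxels nearest a pleural seed point — whose size is the requested
`lesion_extent`, split into contiguous ground-glass (mean −650 HU),
reticulation (additive periodic lattice, amplitude 150 HU, period 4
voxels) and honeycombing (packed air cysts at −950 HU, radius 2–4 voxels,
−300 HU walls) sub-regions. The texture parameters are not anatomical
measurements: they are chosen to straddle the −950/−150 mask window so
lesions stay inside the mask while differing strongly in texture
statistics. What passing tests on phantoms demonstrate is that the
*pipeline* responds to texture differences monotonically and recovers
planted structure — not that the features would rank identically on real
HRCT, which has vessels, airways, gravity gradients and scanner effects
the phantoms deliberately omit.

### Cohorts

`generate_cohort()` draws the two GAP groups with pulmonary function
centered on the study's group statistics (GAP1: FVC 98 ± 18, DLCO 79 ± 19,
FEV1 93 ± 16, TLC 94 ± 21; GAP2: 65 ± 26, 56 ± 23, 61 ± 11, 57 ± 23
percent predicted; median ages near 58 vs 68; predominantly female).
Records are rejection-sampled until the GAP calculator applied to the
record's own gender/age/FVC/DLCO reproduces the intended stage, so
generator labels and `gap_points()` agree on 100% of records by
construction. A single severity latent — the pulmonary-function deficit —
drives each record's phantom lesion extent and shifts its texture mix
toward honeycombing, keeping the image-side signal coupled to the
clinical labels.

### Planted feature tables

`generate_feature_table()` builds the stand-in for an extracted feature
table: informative features with standardized class separation `d`,
correlated clusters, and iid noise. Nuisance clusters are a shared latent
plus `Normal(0, 0.5)` noise, giving pairwise correlation 0.8 by
construction (comfortably above the pipeline's 0.60 clustering
threshold). In the `informative_in_clusters` mode used by the end-to-end
funnel test, the class shift is placed on the planted member only
(`u + d*class`), with companions sharing just the class-independent latent
`u`. This was a deliberate design choice: if companions carried the same
class signal as the planted member, they would be statistically
near-exchangeable predictors, and with a six-patient minority the
Gini-based representative choice within a cluster would be a coin flip —
no selection procedure could be expected to find the planted member.
Putting the signal on one member makes "the cluster's best feature" a
well-defined ground truth the funnel can be scored against.

## Class balancing: MWMOTE

The study cohort is heavily imbalanced (54 GAP1 vs 6 GAP2, ratio 0.11).
`mwmote_oversample()` implements majority-weighted minority oversampling:
noisy minority points (no minority among their `k1 = 5` nearest
neighbours) are excluded; the `k2 = 3` nearest majority neighbours of the
remainder form the borderline majority; their `k3` nearest minority
neighbours (default: half the minority, rounded up — the original
fixed default is meaningless for a 6-point minority) form the informative
minority, which receives selection weights combining closeness to the
class border and local density (`cf_th = 5`, `cmax = 2`). Minority points
are clustered by average linkage cut at `cp = 3` times the mean
nearest-neighbour distance, and each synthetic is a convex combination
`x + alpha (z − x)` of two cluster-mates. All hyper-parameters sit in
`augmentation_config()`; the defaults follow the algorithm's original
publication where the study is silent. Properties verified by tests:
originals preserved verbatim, synthetic count exact, every synthetic a
convex combination of two minority cluster-mates (via recorded
provenance), determinism under a fixed seed. A singleton minority falls
back to duplication with a warning. Distance ties break by index order.

## Selection and modeling

The analysis order follows the study: augment, then split 0.7:0.3
stratified (54/54 → 38+38 train, 16+16 test), then fit all selection
machinery on the training split only. Z-scoring moments come from the
training split and are applied unchanged to test and original data; a
canary test asserts that perturbing test rows cannot change the fitted
moments or the transformed training data.

**Boruta.** No reference implementation is available here, so the
algorithm is implemented directly: each run appends a permuted shadow copy
of every feature, fits a ranger random forest (impurity importance — the
"Gini index" language of the representative step — 500 trees by default),
and scores a hit when a real feature beats the best shadow. Hits are
tested against Binomial(runs, 1/2) two-sided at `alpha = 0.05` with
Bonferroni correction over the still-undecided features, starting at run
5; the loop stops early when nothing is undecided, and anything still
tentative after `max_runs = 100` is resolved by comparing its median
importance to the median best-shadow importance. Calibration is verified
by simulation: with permuted labels, confirmations average at the alpha
level; with five planted features at `d = 2`, all five are confirmed and
over 90% of noise rejected in at least 90% of seeded runs.

**Correlation clusters and representatives.** Confirmed features are
clustered by average-linkage on `1 − |Pearson r|`, cut at
`1 − 0.60`. Absolute correlation and average linkage are this package's
documented choices; the study states only the threshold. Each cluster's
representative is the feature with the highest impurity importance in a
forest fitted on the cluster's features alone, with `mtry` equal to the
cluster size: when every split considers all members, importance
concentrates on the member that genuinely separates the classes instead
of being shared at random among collinear copies. Ties break
lexicographically, which makes the choice deterministic.

**Models.** Logistic regressions are fitted by IRLS (`glm`, tolerance
1e-8, 100 iterations max) for every requested term set and ranked by
`AIC = 2k − 2 log L`. Quasi-complete separation is flagged (divergent
coefficients or non-convergence) but the AIC at the capped iteration is
still reported, mirroring how a collinear two-feature model shows up in
practice. ROC analysis reports the trapezoidal (Mann–Whitney) AUC with a
stratified nonparametric bootstrap percentile 95% CI (2000 replicates by
default) and the sensitivity/specificity at the Youden-J optimum — the
operating-point rule is unstated in the study; Youden is the standard
reproducible choice. Accuracy is estimated by stratified 10-fold
cross-validation with an exact binomial CI, refitting the model per fold
so every sample is scored exactly once. The train-fitted model is
evaluated on train, test and original (non-augmented) data under those
explicit tags, since reports of "original dataset" performance otherwise
leave the provenance of the fit ambiguous.

## Clinical scoring

`gap_points()` transcribes the published GAP point table (shipped as an
editable structure, since staging tables get revised): female 0 / male 1;
age ≤60 → 0, 61–65 → 1, >65 → 2; FVC% ≥75 → 0, 50–74 → 1, <50 → 2;
DLCO% >55 → 0, 36–55 → 1, ≤35 → 2, unable to perform → 3; stages I/II/III
at 0–3 / 4–5 / 6–8 points. The coarseness score sums per-lobe grades
(0 normal … 4 honeycombing) and rescales by
`sum(grades) / n_involved * 6`, so it ranges 0–24, equals six times the
mean grade of involved lobes, and is invariant to appending uninvolved
lobes. Fibrosis extent is dichotomized strictly above 20% ("more than
20%" is strict, so exactly 20% classifies as mild). Group comparisons use
the *unpaired* Wilcoxon rank-sum test for continuous variables — the
study names paired tests for what are independent groups, which cannot be
reproduced literally — and chi-squared without continuity correction for
categorical ones, falling back to Fisher's exact test when any expected
cell is below 5.

## Problem sizes used in tests and the acceptance script

The validation suite runs on deliberately small instances chosen to keep
a full check under a few minutes of one core while leaving each property
statistically sharp: oracle equivalence on 4³–5³ random volumes over ~150
seeded draws; the lesion-extent calibration on 64³–100³ phantoms; Boruta
recovery and null calibration over 10 seeded repetitions at 30 runs × 100
trees; the end-to-end funnel over 10 seeded repetitions at 60 runs × 300
trees; the pipeline smoke test on twelve 32³ phantoms. The acceptance
script extracts all 1116 features from one 64³ phantom and runs the
complete funnel once at 60 runs × 300 trees with 2000 bootstrap
replicates.

## Known limitations

* Phantoms contain no airways, vessels or scanner noise model; left-lung
  geometry and cardiac artifacts are out of scope.
* Feature definitions follow the conventional formulas; the mapping to any
  particular certified lexicon is documented, not asserted.
* Texture distances beyond 1 voxel and regularized or nonlinear
  classifiers are out of scope.
* The numeric results of the original patient cohort (feature values,
  AUCs) are not reproducible without the patient CTs; the package
  reproduces the *procedure* and its procedure-determined counts, and
  validates the machinery on synthetic ground truth instead.
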
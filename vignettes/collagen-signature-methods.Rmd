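---
title: "Methods: collagen signature modeling from SHG-style images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen signature modeling from SHG-style images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collagensig)
```

## The problem

Papillary thyroid carcinoma (PTC) frequently metastasizes to central lymph
nodes, and the decision to perform prophylactic central neck dissection
hinges on predicting central lymph node metastasis (CLNM) before or during
surgery. Conventional clinicopathological predictors — tumor size, location
within the gland, thyroid capsular invasion (TCI) — discriminate only
moderately. Second harmonic generation (SHG) microscopy images fibrillar
collagen label-free, and the architecture of collagen at the invasive
margin (crosslinking, alignment, texture) carries information about the
tumor microenvironment's invasive remodeling.

`collagensig` implements the full analysis chain for this setting:

1. quantify collagen architecture in grayscale SHG-style ROI images through
   a fixed vocabulary of 142 features;
2. average five ROIs per patient, standardize on the training cohort only,
   and select features by L1-penalized (LASSO) logistic regression into a
   scalar **collagen signature**;
3. integrate the signature with the clinical covariates in a multivariate
   logistic model, re-parameterized as a points-based nomogram;
4. evaluate discrimination (ROC/AUC, C-index, DeLong comparison),
   calibration, classification metrics, and net clinical benefit (decision
   curve analysis).

Because real SHG cohorts are not distributable, the package ships a
first-class simulator that generates SHG-like fiber images and whole
patient cohorts with known ground truth; every downstream claim in the test
suite is checked against that ground truth or against independent oracles.

## The synthetic data generator

`simulate_fiber_image()` renders bright curvilinear fibers on a dark
background. Fibers are discrete random walks with unit pixel steps: the
initial axis is drawn from a doubled-angle von Mises distribution (axes,
not directions, are modeled, since fibers are undirected), and each step
turns by a `N(0, curvature_sd)` increment. The polyline is stamped with an
isotropic Gaussian footprint, accumulated by pixelwise max, which yields a
ridge with a Gaussian cross-profile whose full width at half maximum is
`width_mean`. Crosslinks are realized generatively: `crosslink_rate x
n_fibers` branch fibers (Poisson-distributed) start at random points on
existing fibers, and each branch point is recorded as a ground-truth
crosslink. Additive Gaussian background noise (optionally Poisson-like
speckle) is clipped to the 8-bit range `[0, 255]`.

Defaults emulate the imaging design the package targets: a
1000 um x 1000 um field of view at 512 x 512 px (1.95 um/px), 8-bit
gray. Every simulator output is a pure function of `(params, seed)`.

`simulate_cohort()` builds patients: a latent standard-normal *stromal
aggressiveness* score drives both the fiber architecture (through a
deterministic monotone map: crosslink rate up, orientation concentration
down, fiber brightness down) and, together with Bernoulli clinical
covariates, the CLNM log-odds. Default covariate prevalences (size > 1 cm
0.47, upper-lobe location 0.26, TCI 0.49) and a ~41% CLNM prevalence match
the cohort structure of the study design this package emulates; covariates
with no outcome effect (age, sex, BMI, multifocality) are simulated at
realistic prevalences for null-association checks. Outcome coefficient
signs follow the biology: aggressiveness, size, upper location and TCI all
increase risk.

**What the simulator does not emulate**: optical physics (no point-spread
function, no polarization dependence), H&E context, intensity calibration
(gray levels are arbitrary units by design), spatially correlated noise,
and fiber bundling/waviness beyond the random-walk model. Passing tests
therefore demonstrate correctness of the measurement and modeling chain on
a controlled substrate, not performance on real SHG images.

## Segmentation and fiber tracing

- **Mask**: global Otsu threshold on the gray histogram, then connected
  components smaller than `min_object_px` (default 16 px) are removed
  (8-connectivity). A constant or all-background image yields an empty
  mask plus a warning, never an error; downstream features then take
  documented convention values with degeneracy flags.
- **Skeleton**: Zhang-Suen topology-preserving thinning, followed by a
  staircase cleanup that removes pixels whose skeleton neighbours form a
  single 8-connected clump. Without the cleanup, oblique runs retain
  redundant corner pixels that masquerade as degree-3 junctions and
  inflate crosslink counts.
- **Spur pruning**: endpoint-to-junction chains shorter than `spur_min_um`
  (default 4 um) are removed iteratively.
- **Junctions ("crosslinks")**: skeleton pixels with >= 3 neighbours.
  Adjacent junction pixels always collapse (they are one structural
  junction); junctions closer than `node_merge_um` (default 3 um) merge to
  their centroid by single-linkage. The branch-point reading of
  "crosslink" follows the SHG image-analysis literature; it is a modeling
  choice, since a junction in a 2-D projection need not be a biochemical
  crosslink.
- **Fibers**: node-to-node/endpoint skeleton chains, greedily merged across
  junctions when the continuation bends by at most `merge_angle_tol`
  (default 20 degrees), so crossing fibers are traced through their
  intersection (an X yields two fibers and one crosslink). Centerlines are
  smoothed with a 5-px moving average before measuring length — the raw
  8-connected staircase otherwise inflates path length by up to ~8% for
  oblique fibers. Width is twice the mean Euclidean distance-transform
  value along the centerline; orientation is the length-weighted
  doubled-angle mean axis; straightness is chord length over path length.
  Fibers shorter than `fiber_min_um` (default 10 um) are discarded.

All thresholds above are physical lengths. They are calibrated for the
default ~2 um/px resolution; when the same 1000 um field is rendered at a
coarser desk-scale resolution (e.g. 64 px, 15.6 um/px, used for cohort-
scale simulations), the suite passes proportionally larger values
(`spur_min_um = 35`, `fiber_min_um = 40`, `node_merge_um = 20`) so the
thresholds stay at 2-3 pixels.

## The 142-feature vocabulary

`extract_feature_vector()` always returns the same 142 named, finite
values (`feature_schema()`), partitioned 8 morphological + 6 intensity +
128 textural:

- **Morphology (8)**: collagen area fraction; fiber number; mean length
  (um); mean width (um); mean straightness; crosslink density (junctions
  per mm^2 of collagen area); crosslink space (mean nearest-neighbour
  distance among junctions, um); arrangement (length-weighted circular
  variance of doubled orientations, 0 = aligned, ~1 = isotropic).
- **Intensity (6)**: mean, variance, skewness, kurtosis (plain fourth
  standardized moment) of masked pixels; energy `sum(p^2)` and entropy
  `-sum(p log2 p)` over a 256-bin histogram of masked pixels.
- **GLCM (80)**: symmetric, normalized co-occurrence matrices at distances
  1-5 px and angles 0/45/90/135 degrees on the image quantized to 32
  uniform levels over its observed range. Statistics: contrast,
  correlation, energy (angular second moment) and uniformity, read as the
  inverse-difference moment (homogeneity) to keep it distinct from energy.
  The GLCM is computed over the whole ROI, not the mask: co-occurrence at
  a fixed offset is ill-defined over an irregular mask.
- **Gabor (48)**: mean and population variance of the response magnitude
  of a complex Gabor bank at wavelengths 2/4/8/16 px and orientations
  0-150 degrees in 30-degree steps (bandwidth 1 octave, aspect ratio 0.5),
  computed by FFT with circular boundary. The kernel definition is exposed
  as `gabor_kernel()` so direct-convolution checks are possible.

Degenerate inputs take fixed conventions (all flagged): empty mask gives
zero morphology/intensity; a constant image gives GLCM contrast 0,
correlation 0, energy 1, uniformity 1, and near-zero Gabor variances.

One naming note: the feature `glcm.contrast.d2.a45` is the contrast of the
45-degree GLCM at pixel distance 2. Reports of this feature family
sometimes conflate "distance" and "direction" indices; the schema here
fixes distance-then-angle naming and keeps it stable.

Patient-level features are the element-wise arithmetic mean of the (five)
ROI vectors.

## Signature construction

Standardization is strictly train-only: `fit_normalizer()` learns
per-feature means and sample standard deviations on the training cohort
and is then applied unchanged everywhere (zero-variance features are
dropped and listed). `fit_lasso_signature()` runs L1-penalized logistic
regression (glmnet) on the standardized training matrix with a 100-point
penalty grid log-spaced from the smallest all-zero penalty down by 1e-4,
picking the penalty that minimizes mean 5-fold cross-validated binomial
deviance. The minimum rule (rather than the 1-SE rule) is used because the
pipeline reports a single optimal `log(lambda)`. Folds are stratified by
outcome and seeded; identical data and seed reproduce the selected set and
coefficients bit for bit. The signature is the standard linear formula:
intercept plus the sum of selected coefficients times Z-scores. The
cohort-specific optimal penalty of any particular run is a report field,
not a target.

## Clinical modeling and the nomogram

`split_cohort()` assigns `round(0.6 n)` patients to training by simple
seeded randomization (350 patients split 210/140); balance is checked, not
enforced, matching the reporting convention for randomized splits.
Univariate and multivariate logistic models use `stats::glm` with Wald
odds ratios, 95% CIs and p-values; separation and non-convergence are
flagged (`unstable`), constant predictors and collinear designs are
errors. The prespecified multivariate set is {signature, location, size,
TCI}, entered prespecified; a `full_variable_entry` flag admits all
covariates instead, since a univariate-p-gated entry rule cannot be
distinguished from a prespecified one at this remove — neither mode is
claimed as "the original".

The nomogram maps each variable's contribution `beta x` linearly to
points, anchored so the least risky observed value scores 0 and scaled so
the largest contribution span over the training data is 100 points; total
points map back through the logistic function. The construction is an
exact re-parameterization: nomogram and model probabilities agree to
1e-9 by test.

## Evaluation

- **AUC**: Mann-Whitney concordance with half credit for ties (midranks);
  the C-index is the same quantity for binary outcomes and is exposed as a
  named alias. The apparent C-index is reported; a separate
  optimism-corrected training C-index is deliberately not emitted because
  the held-out testing cohort already provides the honest estimate of
  out-of-sample discrimination.
- **Bootstrap CIs**: percentile intervals from 1000 label-stratified
  resamples (percentile rather than BCa: minimal assumptions, matching
  the convention of "1000 bootstrap resamples"); degenerate single-class
  resamples are redrawn and counted.
- **DeLong test** for paired AUCs via placement values, two-sided normal
  reference; the degenerate zero-variance, zero-difference case returns
  p = 1.
- **Classification metrics** (sensitivity, specificity, PPV, NPV,
  accuracy) at a threshold chosen by Youden's J on the training cohort and
  applied to both cohorts (the threshold rule is configurable; Youden is
  the default because clinical reports of this metric family rarely state
  an explicit threshold rule).
- **Calibration** by deciles of predicted risk (quantile bins, empty bins
  merged by construction).
- **Decision curves**: net benefit `TP/n - FP/n * t/(1-t)` against
  treat-all and treat-none references, thresholds strictly inside (0, 1).

## Verification strategy and problem sizes

The suite checks every layer against an independent route:

- GLCM statistics against brute-force pair enumeration on all 512 binary
  3x3 images (exact) and random images; Gabor responses against direct
  circular convolution on 64 x 64 gratings (1e-6); AUC against explicit
  pair enumeration at n <= 30 (exact).
- DeLong and multivariate Wald type-I error calibrated to 0.05 +/- 0.02
  over 500 null simulations each; bootstrap AUC CI coverage >= 93% over
  200 binormal replicates (B = 500, n = 100).
- Multivariate logistic recovery of known generative log-odds within 10%
  at n = 2000 (50 replicates); LASSO signature on a synthetic
  210/140-patient cohort with 5 informative features among 142 reaches
  test AUC > 0.75 with a sparse selection.
- End-to-end: on ten simulated 350-patient cohorts (5 ROIs each, 64 px
  desk-scale rendering), the integrated signature + clinical model beats
  the clinical-only model on test AUC in at least 9 of 10 seeds.

These problem sizes (64 px cohort images, 500-replicate calibrations,
B = 500 coverage checks) are the package's chosen desk-scale conditions:
large enough for the statistical bands above, small enough that the whole
suite runs in minutes on one core.

## Known limitations

- Fiber tracing operates on a 2-D skeleton: overlapping fibers crossing at
  shallow angles can merge or fragment, and junction counts in projection
  overestimate true 3-D crosslink density.
- Otsu segmentation assumes a roughly bimodal histogram; very sparse or
  very dense collagen shifts the threshold and the area-dependent
  features with it.
- Gabor filtering uses circular (wrap-around) boundaries; for images
  smaller than twice the largest wavelength the kernel support is
  effectively clipped (a warning is raised).
- The simulator's link from latent aggressiveness to architecture is
  deliberately simple and monotone; it validates directionality and
  machinery, not effect sizes on real tissue.
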
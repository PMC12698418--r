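# collagensig

Collagen-signature modeling from second-harmonic-generation (SHG) style
microscopy images, for predicting central lymph node metastasis (CLNM) in
papillary thyroid carcinoma (PTC).

SHG microscopy visualizes fibrillar collagen label-free. At the invasive
margin of a thyroid tumor, the *architecture* of that collagen — how
crosslinked, aligned, bright and textured it is — reflects the stromal
remodeling that accompanies lymphatic spread. `collagensig` turns grayscale
ROI images of that margin into a quantitative risk model:

1. **Feature extraction** — each ROI is segmented (Otsu + small-object
   removal), skeletonized, and traced into fibers and junction
   ("crosslink") points; 142 features are computed per ROI: 8 morphological
   (area, number, length, width, straightness, crosslink density, crosslink
   space, arrangement), 6 intensity (mean, variance, skewness, kurtosis,
   energy, entropy) and 128 textural (GLCM contrast/correlation/energy/
   uniformity at 5 distances x 4 angles; Gabor response mean/variance at
   4 scales x 6 orientations). Five ROIs per patient are averaged.
2. **Collagen signature** — features are Z-scored with training-cohort
   parameters only, and an L1-penalized (LASSO) logistic regression with
   5-fold cross-validated penalty selection picks a sparse feature set. The
   signature is the linear predictor
   `sig = b0 + sum_i b_i z_i` over the selected, standardized features.
3. **Integrated model** — a multivariate logistic model of CLNM on the
   signature plus tumor location, tumor size (> 1 cm) and thyroid capsular
   invasion, re-parameterized as a points-based nomogram
   (largest covariate span = 100 points).
4. **Evaluation** — ROC/AUC and C-index with 1000-resample bootstrap CIs,
   DeLong tests between models, Youden-thresholded classification metrics,
   decile calibration curves and decision-curve analysis.

Because real SHG cohorts cannot be shipped, the package includes a
simulator (`simulate_fiber_image()`, `simulate_cohort()`) that renders
SHG-like fiber fields with known ground truth (fiber centerlines,
orientations, true crosslinks, latent per-patient stromal aggressiveness,
true outcome probabilities). The entire pipeline is exercised and tested
against that ground truth and against independent oracles (pair-enumeration
GLCM, direct-convolution Gabor, pairwise-enumeration AUC, permutation
DeLong).

## Worked example

```r
library(collagensig)

# one SHG-like ROI with ground truth
p <- fiber_field_params(n_fibers = 30, crosslink_rate = 1)
sim <- simulate_fiber_image(p, seed = 7)
fv <- extract_feature_vector(sim$image, pixel_size_um = sim$image$pixel_size_um)
round(fv[c("morph.number", "morph.crosslink_density", "morph.arrangement")], 2)
#>            morph.number morph.crosslink_density       morph.arrangement
#>                  161.00                 1525.99                    0.46

# a full synthetic study at desk scale (64 px rendering of the 1000 um FOV)
cfg <- pipeline_config(
  seed = 1,
  simulation = list(n_patients = 350, image_size_px = 64, n_fibers = 25),
  segmentation = list(spur_min_um = 35, fiber_min_um = 40, node_merge_um = 20),
  evaluation = list(bootstrap = 200))
res <- run_pipeline(cfg)
res
#> <pipeline_result: 350 patients (train 210 / test 140), 9 features selected>
#>   signature AUC: train 0.793, test 0.679
#>   integrated vs clinical test AUC: 0.750 vs 0.665 (p=0.085)
```

The printed summary reads: the cohort split 210/140 under the 6:4 rule; the
LASSO kept 9 of 142 features; the collagen signature alone discriminates
CLNM (AUC well above 0.5 on held-out patients); and adding the signature to
the clinical covariates improves test-cohort discrimination over the
clinical-only model — the qualitative ordering the method is designed to
detect. `run_pipeline(cfg, out_dir = "run1")` additionally writes feature
tables, the serialized signature model, OR/CI/p association tables,
classification-metric tables, calibration and decision curves, and a
manifest with the config and seeds.

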
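# boneTexture

Texture-based estimation of bone mineral density (BMD) and bone mineral
content (BMC) from 2D CT slices, for research on opportunistic
osteoporosis screening. Abdomen/pelvis CT acquired for unrelated
indications images the trabecular bone of the spine and proximal femur;
the Hounsfield-unit (HU) distribution and spatial texture of that
compartment carry a density signal that can be regressed against
DXA-style reference values. This package implements the full pipeline -
ROI isolation, 45-feature texture extraction, linear-regression
estimation, correlation-based feature ranking - together with a synthetic
trabecular phantom generator so every stage runs and validates without
clinical data.

Intended users: medical-image-analysis and radiomics researchers who want
a tested, deterministic reference implementation of the
HU-texture-to-BMD pathway, or a controllable synthetic benchmark for
their own estimators.

## The model

Per rectangular trabecular ROI, 45 features are extracted:

* 5 histogram features: mean, sd, skewness, excess kurtosis (population
  moments), and 256-bin Shannon entropy (bits);
* 40 gray-level co-occurrence matrix (GLCM) features: the ROI is
  discretized to *n* levels by equal-width binning of its range; the
  symmetric GLCM `p(i,j)` counts adjacent pixel pairs (distance 1,
  horizontal or vertical) with levels *i*, *j*; 8 GLCMs
  (n = 16, 32, 64, 128 x two orientations) each yield entropy
  `-Σ p log2 p`, contrast `Σ (i-j)² p`, correlation
  `Σ (i-μr)(j-μc) p / (σr σc)`, homogeneity `Σ p / (1+|i-j|)` and
  variance `Σ (i-μr)² p`.

Features and target are z-scored and an unregularised linear model
`ŷ = w0 + Σ wi xi` is fitted by least squares (QR, minimum-norm on rank
deficiency). Cases with any missing feature, or DXA BMD below
0.15 g/cm², are excluded first. Performance per target is the Pearson
correlation coefficient (CC) of predictions vs reference and the MSE in
original units; feature importance is the per-target Pearson correlation
of each feature with the reference, with top-5 membership counted across
the eight targets.

## Worked example

```r
library(boneTexture)

# one synthetic trabecular ROI and its feature vector
img <- generatePhantom(phantomParams(boneFraction = 0.30, seed = 7))
fv  <- extractFeatureVector(img)
round(fv[c("hist_mean", "hist_sd", "glcm_entropy_32_h",
           "glcm_contrast_32_h", "glcm_correlation_32_h")], 3)
#>             hist_mean               hist_sd     glcm_entropy_32_h
#>               155.227               152.353                 6.676
#>    glcm_contrast_32_h glcm_correlation_32_h
#>                16.625                 0.902

# a full study-scale run: simulate -> extract -> fit -> evaluate -> select
cfg <- runConfig(nCases = 458, seed = 1,
                 phantom = list(gridSize = c(32L, 32L)),
                 outputDir = "bmd_run")
report <- runPipeline(cfg)
report$evaluation
#>                 target    cc     mse   n
#> 1     total_lumbar_bmd 0.668   0.057 458
#> 2     total_lumbar_bmc 0.651 103.989 458
#> 3      total_femur_bmd 0.668   0.042 458
#> 4      total_femur_bmc 0.667  39.924 458
#> 5       femur_neck_bmd 0.634   0.038 458
#> 6       femur_neck_bmc 0.694   0.929 458
#> 7 femur_intertroch_bmd 0.659   0.055 458
#> 8 femur_intertroch_bmc 0.684  11.360 458

head(sort(selectionCounts(report$selection), decreasing = TRUE), 4)
#>          hist_mean      hist_skewness glcm_entropy_128_h       hist_entropy
#>                  8                  8                  7                  6
```

The mean HU of the ROI (~155 HU here) reflects the 30% strut fraction at
~400 HU over marrow at ~50 HU. In the cohort run, each target's CC is the
in-sample correlation between the 45-feature linear estimate and the
DXA-like reference; with the generator's default calibration (population
driver-target correlation 0.65) the fitted CCs land in the mid-0.6s, and
the MSEs are on each target's own clinical scale (g/cm² squared for BMD,
g squared for BMC). The selection counts show which features enter the
top-5 for all eight targets - here the intensity features and
high-level-count GLCM entropies, as expected when density drives both
brightness and texture disorder.

`runPipeline()` writes `features.csv`, one `models/model_<target>.json`
per target, `evaluation.csv`, `selection_correlations.csv`,
`selection_counts.csv` and a `run_log.txt` with the seed and the
case-exclusion audit; reruns with the same config are byte-identical.

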
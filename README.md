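# habitboost

Habitat-based radiomics and gradient-boosted survival classification for
multimodal brain MRI, with a calibrated synthetic phantom generator.

## The problem

Glioblastoma (GBM) patients with the same diagnosis have widely different
survival; imaging heterogeneity — how diffusion, perfusion and contrast
enhancement vary *within* one tumor — carries prognostic signal that a
single whole-tumor statistic misses. The habitat-imaging approach works
on six co-registered maps per subject (post-contrast T1w, T2w, mean
diffusivity MD, fractional anisotropy FA, cerebral blood volume CBV and
flow CBF):

1. **Habitat segmentation.** Within-tumor voxels of each map are
   clustered by 1-D k-means: k = 3 on post-contrast T1 (necrotic <
   non-enhanced < enhancing, by ascending cluster center), k = 2 on MD
   (LMD/HMD) and on rCBV (LrCBV/HrCBV), where rCBV = CBV normalized to
   unit mean over normal-appearing white matter. Intersections define ten
   ROIs, e.g. the low-diffusivity/low-perfusion habitat inside the
   enhancing rim (LMD-LrCBV ∩ CE).
2. **Radiomics.** Per ROI × map: histogram mean, SD, skewness g1 =
   m3/m2^1.5, excess kurtosis g2 = m4/m2² − 3, and GLCM contrast,
   correlation, energy, homogeneity (32 gray levels, four distance-1
   in-plane offsets, symmetric, pooled over axial slices) — 10 × 6 × 8 =
   480 features per subject.
3. **Selection and classification.** Random-forest recursive feature
   elimination (10% of remaining features dropped per round by Gini
   importance) keeps 60 features; a from-scratch logistic gradient
   boosting machine (additive stage-wise trees, Newton leaf steps
   Σr / Σp(1−p), shrinkage ν) predicts the 15-month short/long survival
   class, scored by repeated leave-one-out cross-validation with
   accuracy, precision, recall, F1, Mann–Whitney AUC and Matthews
   correlation.

The cohort the design emulates (29 GBM patients, 16 short- / 13
long-term) is private, so the package includes a phantom generator whose
habitat volumes are drawn from the published group statistics (e.g.
tumor-wide LMD-LrCBV 3.20 ± 0.73 cm³ short vs 2.47 ± 0.88 cm³ long;
within-necrosis HMD-LrCBV 1.01 ± 0.49 vs 1.95 ± 0.77 cm³) and whose
intensity contrasts follow the reported effect directions. Every stage is
tested against the phantoms' voxel-level ground truth; see the methods
vignette (`vignettes/habitat-survival-pipeline.Rmd`) for the generative
model and all numerical conventions.

## Worked example

```r
library(habitboost)

# a 29-subject synthetic cohort (16 short / 13 long survivors)
cohort <- generate_cohort(phantom_spec(seed = 2026))
table  <- cohort_feature_table(cohort, seed = 2027)
table
#> <feature_table: 29 subjects x 480 features (long=13, short=16)>

sel <- rf_rfe(table$x, table$labels, n_select = 60, seed = 904)
sel
#> <rfe_result: 60 features selected in 20 iterations>

report <- repeated_trials(table, eval_config(rfe = TRUE),
                          n_trials = 10, base_seed = 907)
report
#> <cv_report: 10 LOOCV trial(s), n=29 subjects>
#>      accuracy precision recall     f1    auc    mcc
#> mean   0.8759    0.8487 0.9438 0.8936 0.8899 0.7520
#> sd     0.0241    0.0248 0.0198 0.0201 0.0173 0.0491
```

Reading the panel: each of the 10 trials re-runs leave-one-out
cross-validation (selection refit inside every training fold) with
reseeded stochastic components; `mean`/`sd` summarize the trials. An
accuracy of 0.88 on this calibrated cohort says the pipeline recovers the
group separation the generator encodes — it is an analog of, not an
estimate of, performance on clinical data. `plot(report, "roc")` and
`plot(report, "trials")` draw the ROC curve and per-trial accuracies, and
`run_pipeline()` executes the whole chain (phantoms → NIfTI habitats →
feature CSV → selection JSON → CV report) into a run directory with a
checksummed manifest.

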
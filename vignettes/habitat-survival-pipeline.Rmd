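---
title: "Habitat radiomics and boosted survival classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics and boosted survival classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`habitboost` implements a habitat-imaging survival pipeline for
glioblastoma: six co-registered maps per subject (post-contrast T1w, T2w,
mean diffusivity MD, fractional anisotropy FA, cerebral blood volume CBV
and flow CBF) are clustered voxel-wise into intensity habitats, habitat
intersections define ten regions of interest (ROIs), per-ROI histogram and
gray-level co-occurrence (GLCM) texture features are fused into a
480-column table, random-forest recursive feature elimination (RF-RFE)
keeps 60 features, and a logistic gradient-boosting classifier is scored by
repeated leave-one-out cross-validation (LOOCV) against the 15-month
short/long survival dichotomy. Because the clinical cohort this design
emulates is private, the package ships a calibrated synthetic phantom
generator with voxel-level ground truth; every downstream stage is tested
against that ground truth.

This vignette records the scientific and numerical decisions: the
generative model behind the phantoms, the clustering and feature
conventions, the from-scratch ensemble learners, the evaluation protocol,
and the known limitations of what passing tests on phantoms can and cannot
show.

# The phantom generative model

## Volume model

Each subject's tumor is an ellipsoid (axis ratio 1 : 0.9 : 0.8) on a
64×64×64 grid of 1 mm isotropic voxels, partitioned radially into a
necrotic core, an enhancing (CE) shell and a non-enhanced outer margin.
Five habitat volumes are drawn per subject from the published group
statistics (cm^3, mean ± SD):

| ROI | short-term | long-term |
|---|---|---|
| En (enhancing) | 1.51 ± 0.45 | 1.26 ± 0.41 |
| Nec (necrosis) | 2.07 ± 0.59 | 2.64 ± 0.65 |
| LMD-LrCBV (tumor-wide) | 3.20 ± 0.73 | 2.47 ± 0.88 |
| HMD-LrCBV (in necrosis) | 1.01 ± 0.49 | 1.95 ± 0.77 |
| En-HrCBV | 0.65 ± 0.37 | 0.42 ± 0.23 |

Two structural constraints shape the sampler:

* **Nested draws without rejection bias.** A sub-habitat that must sit
  inside a parent compartment (HMD-LrCBV inside necrosis, En-HrCBV inside
  the enhancing shell) is drawn as `0.9 × parent × Beta(a, b)` with the
  Beta moment-matched so the child's marginal mean and SD equal the
  table values exactly while the child can never exceed 90% of its
  parent. Naive reject-and-redraw would be triggered in up to a third of
  long-group draws and would bias the recovered group means, which the
  calibration tests (and the volume-recovery analysis) check to three
  standard errors.
* **The whole-tumor SD is emergent, not prescribed.** The published
  whole-tumor volume (≈6.0 ± 5.1 cm^3) cannot hold jointly with the
  compartment statistics above under per-subject accounting: a tumor
  drawn with SD 5 cm^3 falls below the attainable sum of its own
  compartments for a large fraction of draws even under the most
  favorable (comonotone) coupling. The generator therefore *derives* the
  tumor as compartments + a non-enhancing filler whose mean calibrates
  the whole-tumor mean to the published value; the emergent tumor SD is
  about 1 cm^3. This is the one deliberate departure from the published
  marginals, and it is what makes every other marginal exact.

The tumor-wide LMD-LrCBV volume is allocated across compartments
(roughly 20% to the enhancing shell, a small fixed 0.30 ± 0.10 cm^3
target inside necrosis — a value the published tables do not report — and the
remainder to the non-enhanced margin), each piece placed by seeded region
growing from a random interior voxel of its parent compartment until the
drawn voxel count is met exactly. Region growing guarantees exact target
volumes and (almost always) connected blobs; if the remaining parent
region disconnects, growth jumps to a fresh seed, so a sub-habitat may
rarely be two blobs.

## Intensity model

The tables report effect *directions*, not intensity statistics, so the
per-class intensity tables are package defaults (arbitrary units; MD in
µm²/ms; CBV scaled so normal-appearing white matter has unit mean). Each
map is keyed by one voxel classification — T1c, T2, FA by compartment; MD
by LMD/HMD; CBV, CBF by LrCBV/HrCBV — with a per-subject random effect on
each class mean and additive voxel noise. Class means are ordered so the
k-means naming conventions hold (necrotic < non-enhanced < enhancing on
T1c; LMD < HMD; LrCBV < HrCBV).

Group contrasts follow the reported directions: the short-term group has
lower MD and higher rCBV and CBF in the low-perfusion classes, and higher
T2 in necrosis. Magnitudes are a design choice: the study found these
differences significant at p < 0.05 with n = 16/13, which implies
standardized differences of roughly 0.8 or more; the defaults use about
1.5 between-subject SDs for the MD and rCBV contrasts and 0.5–1.2 for the
secondary ones. Phantom fillers are painted HMD/LrCBV inside the enhancing
rim and HMD/HrCBV elsewhere so that every named ground-truth sub-habitat
coincides exactly with its class-intersection definition.

What the phantoms do **not** emulate: MR physics and artifacts, spatial
noise correlation, registration error, partial-volume mixing at habitat
boundaries, irregular (non-ellipsoidal) lesion geometry, and any coupling
between intensity and volume beyond group membership. Passing tests on
phantoms therefore validate the *pipeline machinery* (segmentation,
accounting, features, selection, cross-validation) and the direction of
group effects — not clinical performance on real data.

# Habitat segmentation

Within-tumor voxels of each map are clustered by one-dimensional k-means:
k-means++ seeding, Lloyd iterations until the maximum center shift is
below 1e-6 (cap 300), best of 10 restarts by within-cluster sum of
squares. On sorted values the assignment step reduces to cut points at
center midpoints, so each iteration is a prefix-sum update. k = 3 on
post-contrast T1 (necrotic / non-enhanced / enhancing), k = 2 on MD
(LMD / HMD) and on rCBV (LrCBV / HrCBV), where rCBV is CBV divided by its
mean over the NAWM mask. Cluster names bind to *sorted* centers, so input
order and label permutations cannot change the named output. Clustering is
pooled 3-D by default; `slicewise = TRUE` reproduces per-slice clustering
with labels harmonized by center ordering (slices with fewer distinct
values than k inherit the pooled cut points). Pooled 3-D is the default
because thin-slice ROIs make per-slice clustering unstable.

The ten-ROI catalog is derived by mask intersection: the three T1c
compartments, the two MD clusters, LrCBV, the three intersection habitats
(LMD-LrCBV in CE, LMD-LrCBV in necrosis, HMD-LrCBV in necrosis) and
En-HrCBV, defined as CE minus LrCBV — the emulated protocol defines the name only
implicitly, and CE ∩ HrCBV is the only reading consistent with its
reported volumes. Empty intersections are flagged with a warning and
produce missing features rather than aborting; the test suite covers the
empty-ROI path explicitly.

An exact 1-D dynamic-programming k-means solver in the test suite serves
as the optimality oracle; restarted Lloyd matches it on ≥99% of seeded
mixture draws (with 50 restarts on small inputs).

# Radiomic features

For each of the 10 ROIs × 6 maps, eight features: histogram mean, sample
SD (n−1), moment skewness g1 and excess kurtosis g2; and GLCM contrast,
correlation, energy and homogeneity — 480 features named
`{roi}__{map}__{feature}`. The three named texture features of the emulated protocol
cannot reach its printed total of 480 under any ROI/map combination
consistent with the ten-ROI catalog, so energy completes the classical
GLCM quartet.

GLCM convention (unspecified in the emulated protocol, fixed here): 32 gray levels by
equal-width quantization over the ROI's own range; four in-plane offsets
at distance 1 ((0,1), (1,0), (1,1), (1,−1)); pairs accumulated over all
axial slices with both voxels in-ROI, counted symmetrically, pooled into
one matrix, then normalized to sum 1. Correlation is defined as 0 when a
marginal SD vanishes; skewness/kurtosis are missing below 3 voxels or at
zero variance; an empty ROI yields a missing 48-feature block. Cohort
assembly imputes missing cells by per-column median, drops all-missing
columns with a warning, and z-scores columns; during cross-validation the
z-scoring is refit on each training fold and applied to the held-out
subject so no test statistics leak into normalization.

Relative and absolute ROI volumes go to a separate per-subject volume
report (the group-table analog) rather than into the ML table, preserving
the 480-column contract. The volume report also includes the tumor-wide
LMD ∩ LrCBV volume, the quantity the group tables report.

# Learners

All tree learners are implemented in the package (CART growing in C++
under `src/`, everything else in R); established libraries
(`randomForest`, `xgboost`) appear only as cross-check oracles in tests.

* **Regression trees**: greedy SSE-reduction splits at midpoints between
  distinct values, leaf value = mean target. An exhaustive-enumeration
  stump oracle verifies split optimality on tiny inputs.
* **Random forest**: bootstrap per tree, Gini splits over
  `mtry = floor(sqrt(p))` random candidates per node, class by majority
  vote; importances are total Gini decrease per feature, averaged and
  normalized to sum 1.
* **RF-RFE**: iteratively drops the `ceiling(0.1 × remaining)`
  lowest-importance features (at least one, never overshooting the
  60-feature target), refitting a 200-tree forest each round; importance
  ties break lexicographically by feature name so selection is
  reproducible.
* **Gradient boosting**: logistic loss, base score = prevalence log-odds,
  residual-fitted depth-limited trees with Newton leaf updates
  `sum(r) / sum(p(1−p))` (denominator floored at 1e-12, steps clipped to
  |γ| ≤ 10), shrinkage ν, optional row subsampling. Training log-loss is
  non-increasing at full sampling, and halving ν while doubling the stage
  count leaves training predictions nearly unchanged — both properties
  are tested.

The default classifier configuration is `M = 200` stages, `ν = 0.05`,
depth 1, subsample 0.8, `min_leaf = 5`. The source names the tunable knobs
but not their values; this default was chosen by comparing grid candidates
with repeated LOOCV on independent synthetic cohorts (generation seeds
disjoint from every seed used in the tests and the acceptance script):
shallow, strongly shrunk ensembles were the most stable on 29-subject
tables, while depth ≥ 2 with 100+ stages overfits the 480-column table
badly. `tune_hyperparameters()` implements stratified inner-CV grid search
(ties toward the smaller stage count, depth and learning rate) for users
who want per-fold tuning; it is off by default because it multiplies the
runtime of an already nested protocol roughly 250-fold and the emulated
protocol tuned once on the full dataset anyway — that leaky variant is
available behind `paper_faithful = TRUE` and logs an explicit warning.

# Evaluation protocol

LOOCV holds out each subject once per trial; inside each fold the
normalization, feature selection and classifier fit see only the n−1
training subjects (the leakage-safe default). Trials are repeated (50 in
the emulated protocol; 10 in the packaged analyses, which is enough to
stabilize the mean at the tested thresholds) with trial-to-trial variation
coming from reseeding the stochastic components — RFE forests and boosting
subsampling; the folds themselves are deterministic, since the emulated protocol does
not state what varied across its repetitions. The metric panel reports
accuracy, precision, recall, F1, Mann–Whitney AUC (ties ½) and Matthews
correlation, for the positive class (short-term survival, the clinically
urgent class) and macro-averaged. Zero-denominator metrics report 0 with a
warning; the classification threshold is fixed at 0.5; ROC points come
from the first trial's pooled held-out probabilities by default
(`pool_roc = "all"` pools across trials). The trapezoidal ROC area equals
the Mann–Whitney AUC, which the tests assert against a pair-counting
oracle.

# Numerical choices and degenerate inputs

* Seeds: every stochastic step derives its seed from a single base seed
  via a fixed integer recurrence (kept below 2^31), so cohorts, fits and
  reports are bit-reproducible.
* k-means: fewer distinct values than k is an error naming the map;
  empty clusters restart at a random data point; ties in center order
  cannot occur at convergence (centers are strictly ordered by the 1-D
  structure).
* Trees: non-finite inputs error; pure or too-small nodes become leaves.
* Metrics: single-class truth gives missing AUC/MCC with a warning;
  single-class training folds predict the majority class with a warning
  rather than aborting a whole report.
* Problem sizes in the packaged analyses: calibration checks use 2000
  volume draws per group; volume recovery uses 200 phantoms per group;
  the classification analog uses the default 29-subject cohort with
  10 LOOCV trials. These sizes put the Monte-Carlo error of each checked
  mean well inside the three-standard-error bands used by the tests.

# Known limitations

* Phantom realism is deliberately minimal (see above); accuracy numbers on
  phantoms are analogs, not estimates of clinical performance.
* The generator reproduces the published compartment marginals and the
  whole-tumor mean, but not the published whole-tumor SD (mutually
  inconsistent with the former, as explained above).
* With 29 subjects, LOOCV accuracy has a standard error of roughly 0.08
  per trial; repeated trials average the stochastic components but not the
  fold structure, so small differences between pipeline variants
  (for example with versus without feature selection) are at the edge of
  resolution at this cohort size.
* Whether the original analysis clustered per slice or pooled, and
  whether selection sat inside or outside the folds, are both unstated;
  both variants are implemented and flagged, with the stabler choice as
  the default.
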
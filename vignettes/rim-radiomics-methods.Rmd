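---
title: "Peritumoral-rim CT radiomics: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral-rim CT radiomics: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(RimRadiomics)
```

## The problem

Endometrial cancers with DNA mismatch-repair deficiency (MMR-D) or high
tumor mutational burden (TMB-H, here > 15.5 mut/Mb) are candidates for
immune checkpoint blockade, but their identification requires sequencing
and immunohistochemistry of tissue. This package implements a
clinical-radiomic analysis that asks whether those phenotypes leave a
measurable imprint on contrast-enhanced CT: quantitative texture features
are extracted from the tumor volume-of-interest (VOI) and, crucially, from
a thin *peritumoral rim* — the 3 mm shell around the tumor contour that
covers the invasive edge — and fed, together with age, histology, grade and
stage, into a recursive-feature-elimination random forest (RFE-RF).

Two binary tasks are supported:

* **mmr** — MMR-D versus the copy-number-based subtypes (CN-low-like,
  CN-high-like); POLE-ultramutated lesions are excluded because they form a
  biologically distinct hypermutated group.
* **tmb** — TMB strictly above 15.5 mut/Mb versus the rest, all subtypes
  included.

Patient CT volumes cannot be redistributed, so the package ships a phantom
generator that reproduces the *statistical structure* the analysis relies
on; every pipeline stage is exercised and tested against those phantoms.

## Pipeline model

For each lesion the steps are:

1. **Resample** volume and mask to 1 mm^3 (trilinear for intensities,
   nearest-neighbor for the mask). Texture statistics are only comparable
   across lesions on a common grid.
2. **Regions**: dilate the tumor VOI by 3 mm — metric dilation via an exact
   Euclidean distance transform, so "3 mm" is a physical length on any
   grid — and subtract the tumor, leaving the rim.
3. **Features**: a fixed 100-statistic panel per region, computed on the
   tumor VOI and on the dilated VOI. Rim features are the *differences*
   `f(dilated) − f(tumor)`, which isolate the shell's contribution; a
   margin-0 dilation gives rim features that are exactly zero.
4. **Selection cascade** (discovery split only):
   Kruskal–Wallis scanner-stability filter → mRMR top-80% → elastic-net
   prefilter; survivors plus encoded clinical covariates are z-scored with
   discovery parameters.
5. **RFE-RF**: nested repeated cross-validation (10 repeats × 5 outer ×
   5 inner = 250 analysis folds) with Gini-importance rankings; features
   selected in strictly more than 10% of the analysis folds are "relevant".
6. **Evaluation**: AUROC with DeLong variance and Wald CIs, the unpaired
   DeLong comparison of training-CV versus held-out AUROC,
   sensitivity/specificity/PPV/NPV with Clopper–Pearson CIs at a 0.5
   operating point, and BH-corrected Mann–Whitney associations of the
   relevant features.

## The feature panel

The per-region panel totals exactly 100 statistics, versioned in
`inst/extdata/feature_manifest.json`:

| family | count | notes |
|---|---|---|
| first-order | 19 | population variance; skewness/kurtosis := 0 on constant regions |
| GLCM | 24 | distance 1, 13 unique 3D directions, symmetric, per-direction features averaged |
| GLRLM | 16 | 13 directions, averaged |
| GLSZM | 16 | zones by 26-connectivity |
| NGTDM | 5 | 26-neighborhoods, out-of-mask neighbors excluded |
| NGLDM | 12 | dependence = equal-level 26-neighbors (alpha 0) |
| Gabor | 8 | mean magnitude per bank element, 4 orientations × {4, 8} mm, 2D per axial slice |

Design choices made where the design was genuinely open:

* **Discretization** — 32 gray levels, within-region min–max equal-width
  binning. A fixed bin *number* keeps texture comparable across lesions
  whose HU ranges differ; 32 is a common CT-era default.
* **Direction aggregation** — features are computed per direction and
  averaged (not computed on a merged matrix); one documented choice among
  the standard aggregation variants.
* **Degenerate statistics** — GLCM correlation on a zero-variance region
  is 0; NGTDM coarseness with a vanishing denominator is 10^6. Constant
  phantom regions then stay finite.
* **Gabor bank** — 4 orientations × 2 wavelengths in 2D per axial slice
  (in-plane CT resolution is where edge content lives), sigma = 0.5
  wavelength, DC-free even kernels so constant images give zero response.
* **Texture gate** — regions below 27 voxels (3×3×3) are rejected: runs,
  zones and neighborhoods are ill-defined below that scale. First-order
  statistics remain defined for any non-empty region.

## Selection cascade parameters

* Stability filter alpha = 0.05, uncorrected: an aggressive filter is the
  conservative harmonization choice, and the type-I cost (≈5% of null
  features removed, verified by permutation tests) is acceptable.
* mRMR in the difference (MID) form with mutual information on 3
  equal-frequency bins; "top 80%" uses a ceiling, and ties break
  lexicographically so the ranking is deterministic.
* Elastic-net prefilter: (alpha, lambda) tuned by repeated stratified
  5-fold CV × 10 with minority upsampling inside training folds only. The
  penalty uses the **one-standard-error rule** — the strongest penalty
  within one SE of the deviance minimum. At the plain minimum the retained
  set under null labels stays large (many near-zero coefficients survive);
  the 1-SE rule prunes the majority of noise while still recovering
  planted log-odds-1.0 effects in ≈98% of simulated runs. Importance is
  the mean absolute standardized coefficient across repeats; importance
  > 0 survives.
* Clinical covariates (age numeric, histology one-hot against an
  endometrioid reference, grade and stage binary) bypass the radiomic
  cascade and are appended before classification.
* All selection and standardization parameters are computed on the
  discovery split only; a leakage audit in the test suite verifies that
  perturbing validation rows changes nothing upstream of prediction.

## Classifier

2000 trees by default (tests and the acceptance script use 200-tree
forests for the structural and recovery checks; the bookkeeping is
identical). Candidate subset sizes follow the geometric grid
{2, 4, 8, 16, 32, all}. Class imbalance is handled with stratified folds
and inverse-frequency class weights — upsampling is used only in the
elastic-net stage. The best subset size per outer fold maximizes mean
inner AUROC; the final size is the mode across outer folds with ties
broken toward the smaller size. A single pipeline seed deterministically
derives every fold assignment and forest seed, so selection frequencies
are exactly reproducible.

The "relevant" set uses the strict rule count > 10% of total analysis
folds (26 of 250 qualifies, 25 does not).

## The phantom generator

`simulationConfig()` defaults encode the study conditions: 150 patients;
subtype proportions 4% POLE, 29.3% MMR-D, 18.7% CN-low-like, 48%
CN-high-like; a 70/30 stratified split; per-class log-normal TMB with the
MMR-D distribution placing ≈90% of its mass above 15.5 mut/Mb and the
CN classes almost entirely below it; three scanner manufacturers with
additive HU offsets and noise-sd multipliers that make intensity-driven
features scanner-unstable (the stability filter's job); and
class-correlated clinical covariates.

Lesions are noisy ellipsoids (radii 6–11 mm, 70 HU on a 30 HU background,
10 HU Gaussian noise) — not anatomically realistic uteri, which is
deliberate: the pipeline consumes only intensities inside and near the
VOI. The class-discriminating signal is *extra high-frequency texture in
the 2 mm peritumoral band just outside the tumor boundary*, with a
per-class amplitude multiplier (default 3× for the hypermutated classes,
1× otherwise, on an 8 HU base). The band sits strictly outside the VOI: a
symmetric shell straddling the boundary would feed half the signal into
the intratumoral features, which then crowd the rim differences out of
the classifier's relevant set — the opposite of the rim-dominated
structure the generator is meant to emulate. With the band outside,
intratumoral features are class-blind by construction, discrimination
must travel through the rim differences, and recovery is testable: the
planted registry records what was injected and the end-to-end test
demands a rim feature in the relevant set.

The phantom radii are smaller than typical endometrial lesions; they were
chosen once so a full 150-lesion cohort extracts in well under a minute,
and the texture statistics the pipeline uses are scale-free within the
panel's neighborhood definitions.

What the phantoms do **not** model: organ anatomy and partial-volume
effects at real tissue interfaces, contrast-phase variation, spatially
correlated (non-white) CT noise, multifocal disease, and any genuine
biological link between boundary texture and mutational state. Passing
tests therefore demonstrate that the pipeline *recovers a known signal of
the hypothesized kind and stays at chance when none exists* — not that
real tumors carry such a signal.

## Null behavior and statistical checks

`nullSimulationConfig()` removes the planted effect, the scanner batch
effect and the clinical-class correlation. On null cohorts the end-to-end
validation AUROC stays within binomial noise of 0.5, and per-feature
Mann–Whitney p-values are marginally uniform. One subtlety: the 200
features of a lesion are strongly cross-correlated, so a Kolmogorov–
Smirnov test of joint uniformity is miscalibrated (it assumes independent
p-values) and rejects even on null cohorts. The tests therefore check
dependence-robust summaries — the fraction of p < 0.05, the median p, and
the absence of BH-significant features.

## Numerical conventions

* Z-scoring uses the sample standard deviation ({1,2,3} → {−1, 0, 1});
  zero-variance columns pass through as 0 with a warning.
* AUROC is the normalized Mann–Whitney U with ties counted 1/2.
* The DeLong comparison is the *unpaired* variant: training-CV and
  held-out scores come from disjoint cohorts. A sample compared against
  itself gives p = 1 exactly; AUROC exactly 0 or 1 degenerates the
  variance and yields p = NA with a warning.
* Mann–Whitney uses exact enumeration below 8 per group (untied), normal
  approximation with tie correction otherwise; constant features get
  p = 1 by convention.
* TMB-H uses the strict inequality > 15.5 mut/Mb.
* The 0.5 operating point for confusion metrics is a documented,
  configurable choice; the original operating point behind printed
  sensitivities is unknowable from summary statistics alone.

## Problem sizes used in tests

Unit tests run on cohorts of 36–60 phantoms and 50–100-tree forests; the
acceptance checks run the printed configurations where they are the point
(250 analysis folds at 10 repeats; 150-lesion cohorts with a 105/45 split
for the end-to-end recovery, 10 cohort seeds, 200-tree forests with 5
repeats inside the end-to-end runs). These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in
minutes.

## Known limitations

* The rim-difference definition makes rim features sensitive to the
  relative volumes of tumor and shell; very large tumors dilute the rim
  contribution.
* Harmonization is subtractive only (feature removal), not corrective
  (no ComBat-style adjustment).
* Only binary tasks; no probability calibration; no survival endpoints.
* 2D Gabor per axial slice ignores through-plane edge content.
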
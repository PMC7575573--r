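# RimRadiomics

Clinical-radiomic classification of endometrial tumors from
contrast-enhanced CT. The package implements, as a tested and reusable
pipeline, an analysis that asks whether mismatch-repair-deficient (MMR-D)
and high-tumor-mutational-burden (TMB-H, > 15.5 mut/Mb) cancers can be
recognized from the texture of the tumor and — especially — of the
**peritumoral rim**, the 3 mm shell around the tumor contour that covers
the invasive edge. It is aimed at imaging scientists who want to run,
stress-test or extend this kind of rim-difference radiomics workflow
without access to patient images: a phantom generator reproduces the
statistical structure the analysis relies on.

## What it computes

For each lesion with CT volume and binary tumor mask (NIfTI-1):

1. resample to 1 mm³; dilate the tumor VOI by 3 mm (exact Euclidean
   distance transform) and subtract it, leaving the rim;
2. extract a fixed 100-statistic panel per region — first-order (19),
   GLCM (24), GLRLM (16), GLSZM (16), NGTDM (5), NGLDM (12) and Gabor (8)
   — on the tumor VOI and the dilated VOI, and form the 200-feature vector

   `x = (f(tumor), f(dilated) − f(tumor))`,

   so rim features isolate the shell's contribution;
3. reduce dimensionality on the discovery split only:
   Kruskal–Wallis scanner-stability filter (alpha 0.05) → mRMR top-80%
   (difference form, MI on 3 equal-frequency bins) → elastic-net prefilter
   (repeated stratified 5-fold CV × 10, minority upsampling in training
   folds, importance = mean |standardized coefficient| > 0), then z-score
   with discovery parameters;
4. classify with a recursive-feature-elimination random forest
   (2000 trees; 10 repeats × 5 outer × 5 inner = 250 analysis folds;
   Gini-importance rankings; features selected in > 10% of analysis folds
   are "relevant");
5. evaluate: AUROC as the normalized Mann–Whitney U, DeLong variance and
   CIs, the unpaired DeLong comparison of training-CV vs held-out AUROC,
   sensitivity/specificity/PPV/NPV with Clopper–Pearson 95% CIs, and
   BH-corrected Mann–Whitney associations for the relevant features.

Two tasks: `mmr` (MMR-D vs CN-low-like/CN-high-like, POLE excluded) and
`tmb` (TMB > 15.5 mut/Mb vs the rest).

## Worked example

```r
library(RimRadiomics)

cohort <- generateCohort(simulationConfig(n_patients = 60, seed = 7))
cohort
#> PhantomCohort: 60 patients
#>   subtypes: CN-high-like=31, CN-low-like=10, MMR-D=12, POLE=7

cfg <- pipelineConfig(task = "tmb",
                      rfe = rfeConfig(nTrees = 200, repeats = 2),
                      prefilterRepeats = 5, seed = 11)
result <- runPipeline(cohort, cfg)

result$selection
#> SelectionReport:
#>   stability  200 -> 152 features
#>   mrmr       152 -> 122 features
#>   prefilter  122 -> 5 features
#>   surviving: 5 features

result$model
#> RFEModel: 4 selected features (best size 4), CV AUROC 0.941, 50 analysis folds

result$evaluation
#> Training (CV) AUROC 0.94 (0.86, 1.00)
#> Test AUROC          1.00 (1.00, 1.00)   DeLong p = 0.15
#>   sensitivity  1.00 (0.54, 1.00)
#>   specificity  1.00 (0.74, 1.00)
#>   ppv          1.00 (0.54, 1.00)
#>   npv          1.00 (0.74, 1.00)
#> Relevant features: 4
```

Reading the output: the 48-phantom discovery split (70%) drives the whole
cascade; 200 radiomic features shrink to 5 survivors, the RFE-RF settles
on a 4-feature forest, and the 18-phantom validation split is scored once
at the end. The default phantom cohort plants extra boundary-shell texture
in the hypermutated classes, which is why held-out discrimination is
near-perfect here; with `nullSimulationConfig()` the same pipeline stays
at chance. Per-feature associations of the relevant set (Mann–Whitney +
BH) are in `result$evaluation$associations`:

```r
head(result$evaluation$associations, 3)
#>                    feature  U            p        p_adj
#> 1 intratumoral_fo_kurtosis 72 0.0001077354 0.0001436472
#> 2               rim_fo_p90 10 0.0134669252 0.0134669252
#> 3      intratumoral_fo_min  0 0.0001077354 0.0001436472
```

A thin CLI over the same functions is at `inst/cli/rimradiomics.R`
(`simulate`, `extract`, `run-all`).

## Method vignette

`vignettes/rim-radiomics-methods.Rmd` documents the model and its
assumptions, every tunable parameter with defaults and rationale, what the
phantom generator does and does not emulate, numerical conventions for
degenerate inputs, and known limitations.
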
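#' The 100-feature per-region panel manifest
#'
#' The panel totals exactly 100 statistics per region, drawn from seven
#' families: first-order (19), GLCM (24), GLRLM (16), GLSZM (16), NGTDM (5),
#' NGLDM (12) and Gabor (8). The full lesion vector is 200-dimensional:
#' each statistic appears once with prefix `intratumoral_` (computed on the
#' tumor VOI) and once with prefix `rim_` (dilated-VOI value minus tumor-VOI
#' value). The manifest is versioned and also shipped as
#' `inst/extdata/feature_manifest.json`.
#'
#' @param region if `"both"` (default) the full 200 ids; `"panel"` gives the
#'   100 per-region statistic ids
#' @return character vector of feature ids
#' @export
featureManifest <- function(region = c("both", "panel")) {
  region <- match.arg(region)
  panel <- c(
    names(firstOrderFeaturesNames()),
    names(glcmFeatureNames()),
    names(glrlmFeatureNames()),
    names(glszmFeatureNames()),
    names(ngtdmFeatureNames()),
    names(ngldmFeatureNames()),
    names(gaborFeatureNames()))
  stopifnot(length(panel) == 100L)
  if (region == "panel") return(panel)
  c(paste0("intratumoral_", panel), paste0("rim_", panel))
}

firstOrderFeaturesNames <- function() {
  stats::setNames(nm = c("fo_mean", "fo_variance", "fo_skewness",
    "fo_kurtosis", "fo_energy", "fo_entropy", "fo_min", "fo_max", "fo_p10",
    "fo_p25", "fo_median", "fo_p75", "fo_p90", "fo_iqr", "fo_range",
    "fo_mad", "fo_rmad", "fo_rms", "fo_uniformity"), object = logical(19))
}
glcmFeatureNames <- function() {
  stats::setNames(nm = paste0("glcm_", c("joint_maximum", "joint_average",
    "joint_variance", "joint_entropy", "difference_average",
    "difference_variance", "difference_entropy", "sum_average",
    "sum_variance", "sum_entropy", "energy", "contrast", "dissimilarity",
    "inverse_difference", "inverse_difference_norm",
    "inverse_difference_moment", "inverse_difference_moment_norm",
    "inverse_variance", "correlation", "autocorrelation", "cluster_tendency",
    "cluster_shade", "cluster_prominence", "info_correlation1")),
    object = logical(24))
}
glrlmFeatureNames <- function() {
  stats::setNames(nm = paste0("glrlm_", c("sre", "lre", "lglre", "hglre",
    "srlgle", "srhgle", "lrlgle", "lrhgle", "gln", "glnn", "rln", "rlnn",
    "rp", "glv", "rlv", "re")), object = logical(16))
}
glszmFeatureNames <- function() {
  stats::setNames(nm = paste0("glszm_", c("sae", "lae", "lglze", "hglze",
    "salgle", "sahgle", "lalgle", "lahgle", "gln", "glnn", "szn", "sznn",
    "zp", "glv", "zv", "ze")), object = logical(16))
}
ngtdmFeatureNames <- function() {
  stats::setNames(nm = paste0("ngtdm_", c("coarseness", "contrast",
    "busyness", "complexity", "strength")), object = logical(5))
}
ngldmFeatureNames <- function() {
  stats::setNames(nm = paste0("ngldm_", c("sde", "lde", "lgle", "hgle",
    "sdlgle", "sdhgle", "ldlgle", "ldhgle", "gln", "dn", "dnn", "de")),
    object = logical(12))
}
gaborFeatureNames <- function() {
  g <- expand.grid(o = c(0, 45, 90, 135), w = c(4, 8))
  stats::setNames(nm = sprintf("gabor_o%d_w%g", g$o, g$w),
                  object = logical(8))
}

computeRegionPanel <- function(volume, mask, nBins = 32) {
  reg <- discretizeRegion(volume, mask, nBins)
  out <- c(firstOrderFeatures(volume, mask, nBins),
           glcmFeatures(reg),
           glrlmFeatures(reg),
           glszmFeatures(reg),
           ngtdmFeatures(reg),
           ngldmFeatures(reg),
           gaborFeatures(volume, mask))
  out[featureManifest("panel")]
}

#' Extract the 200-feature vector for one lesion
#'
#' Computes the 100-statistic panel on the tumor VOI and on the 3 mm-dilated
#' VOI; rim features are the element-wise differences (dilated minus tumor),
#' which isolate the contribution of the peritumoral shell. A margin-0
#' dilation therefore yields rim features that are exactly zero.
#'
#' @param volume a [CTVolume-class] on the analysis grid
#' @param regions a [LesionRegions-class] on the same grid
#' @param nBins gray levels for texture discretization
#' @return named numeric vector of exactly 200 finite features
#' @export
extractLesionFeatures <- function(volume, regions, nBins = 32) {
  stopifnot(is(regions, "LesionRegions"))
  ft <- computeRegionPanel(volume, regions@tumor, nBins)
  fd <- computeRegionPanel(volume, regions@dilated, nBins)
  out <- c(stats::setNames(ft, paste0("intratumoral_", names(ft))),
           stats::setNames(fd - ft, paste0("rim_", names(ft))))
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(head(names(out)[bad], 5), collapse = ", "))
  out
}

#' Extract features for a whole phantom cohort
#'
#' Runs region construction and feature extraction per lesion and assembles a
#' `SummarizedExperiment` with the 200-feature assay (features x lesions) and
#' the clinical covariates as column data.
#'
#' @param cohort a [PhantomCohort-class]
#' @param margin rim dilation margin in mm
#' @param nBins gray levels for texture discretization
#' @param resample if `TRUE`, volumes are first resampled to 1 mm^3
#' @return a [SummarizedExperiment::SummarizedExperiment-class]
#' @export
extractCohortFeatures <- function(cohort, margin = 3, nBins = 32,
                                  resample = TRUE) {
  stopifnot(is(cohort, "PhantomCohort"))
  n <- nrow(cohort@clinical)
  mat <- matrix(NA_real_, nrow = 200L, ncol = n,
                dimnames = list(featureManifest("both"),
                                cohort@clinical$patient_id))
  for (k in seq_len(n)) {
    vol <- cohort@volumes[[k]]
    msk <- cohort@masks[[k]]
    if (resample && any(abs(vol@spacing - 1) > 1e-9)) {
      rs <- resampleIsotropic(vol, msk, 1)
      vol <- rs$volume; msk <- rs$mask
    }
    regions <- makeRegions(msk, margin)
    mat[, k] <- extractLesionFeatures(vol, regions, nBins)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(radiomics = mat),
    colData = S4Vectors::DataFrame(cohort@clinical,
                                   row.names = cohort@clinical$patient_id))
}

#' Feature matrix of a cohort feature table, lesions in rows
#'
#' @param se the `SummarizedExperiment` from [extractCohortFeatures()]
#' @return numeric matrix, lesions x features
#' @export
featureMatrix <- function(se) {
  t(SummarizedExperiment::assay(se, "radiomics"))
}
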
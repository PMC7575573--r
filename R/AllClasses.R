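#' @import methods
#' @importFrom stats quantile sd var median rnorm runif rlnorm kruskal.test
#'   wilcox.test p.adjust binom.test pnorm qnorm predict fft
#' @importFrom utils head write.csv read.csv
#' @useDynLib RimRadiomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' CT volume in Hounsfield units
#'
#' A 3D scalar grid of CT intensities with voxel spacing and world origin.
#' Voxel centers sit at \code{origin + (index - 1) * spacing} (1-based array
#' indices, 0-based physical offsets); orientation is assumed RAS as produced
#' by the NIfTI affine.
#'
#' @slot voxels 3D numeric array of intensities (HU).
#' @slot spacing numeric(3), voxel size in mm per axis; all > 0.
#' @slot origin numeric(3), world coordinate of the first voxel center (mm).
#'
#' @seealso [readVolume()], [writeVolume()], [resampleIsotropic()]
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("CTVolume", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L)
    return("origin must be a numeric triplet (mm)")
  if (any(!is.finite(object@voxels)))
    return("intensities must be finite")
  TRUE
})

#' Binary volume-of-interest mask
#'
#' A binary tumor segmentation aligned voxel-for-voxel with its parent
#' [CTVolume-class]. Stored as 0/1 integers.
#'
#' @slot voxels 3D array with values in \{0, 1\}.
#' @slot spacing,origin as in [CTVolume-class].
#'
#' @export
setClass("VOIMask", contains = "CTVolume")

setValidity("VOIMask", function(object) {
  if (!all(object@voxels %in% c(0, 1)))
    return("mask voxels must be 0 or 1")
  TRUE
})

#' Tumor, dilated and peritumoral-rim masks for one lesion
#'
#' The rim is the dilated mask minus the tumor mask: the shell obtained by
#' expanding the tumor contour by `margin` mm. Set identities
#' (tumor subset-of dilated; rim = dilated and-not tumor) hold exactly.
#'
#' @slot tumor,dilated,rim [VOIMask-class] objects on a common grid.
#' @slot margin dilation margin in mm.
#'
#' @seealso [makeRegions()]
#' @export
setClass("LesionRegions",
  representation(tumor = "VOIMask", dilated = "VOIMask", rim = "VOIMask",
                 margin = "numeric"))

setValidity("LesionRegions", function(object) {
  t <- object@tumor@voxels; d <- object@dilated@voxels; r <- object@rim@voxels
  if (!identical(dim(t), dim(d)) || !identical(dim(t), dim(r)))
    return("tumor, dilated and rim must share one grid")
  if (any(t > d)) return("tumor must be a subset of the dilated mask")
  if (any(r != d - t)) return("rim must equal dilated minus tumor")
  if (object@margin < 0) return("margin must be >= 0")
  TRUE
})

#' Synthetic cohort of CT tumor phantoms
#'
#' Holds per-patient phantom volumes and masks together with a clinical table
#' (age, histology, grade, stage, scanner, molecular subtype, TMB in mut/Mb)
#' and a registry of the texture effects that were planted, so recovery tests
#' can check that the pipeline finds what was injected.
#'
#' @slot volumes list of [CTVolume-class].
#' @slot masks list of [VOIMask-class].
#' @slot clinical data.frame with one row per patient.
#' @slot registry list describing the planted effects.
#' @slot config the [simulationConfig()] list used.
#'
#' @seealso [generateCohort()]
#' @export
setClass("PhantomCohort",
  representation(volumes = "list", masks = "list", clinical = "data.frame",
                 registry = "list", config = "list"))

setValidity("PhantomCohort", function(object) {
  n <- nrow(object@clinical)
  if (length(object@volumes) != n || length(object@masks) != n)
    return("volumes, masks and clinical rows must agree in length")
  if (n > 0 && any(!vapply(object@masks,
                           function(m) sum(m@voxels) > 0, logical(1))))
    return("every mask must be non-empty")
  if (n > 0 && any(object@clinical$tmb < 0))
    return("TMB must be >= 0")
  TRUE
})

#' Feature-selection cascade report
#'
#' Records, for each stage of the dimensionality-reduction cascade
#' (scanner-stability filter, mRMR ranking, elastic-net prefilter), the
#' features going in and out and the per-feature scores, plus the ordered
#' surviving feature list.
#'
#' @slot stages named list; each element has `features_in`, `features_out`,
#'   and a named numeric `scores` vector.
#' @slot surviving character vector of surviving feature ids, in rank order.
#'
#' @export
setClass("SelectionReport",
  representation(stages = "list", surviving = "character"))

#' Fitted recursive-feature-elimination random forest
#'
#' @slot forest the final `ranger` forest fit on the full discovery set.
#' @slot selected character vector of feature ids in the final model.
#' @slot bestSize modal best subset size across outer folds.
#' @slot cvAUROC cross-validated AUROC from pooled outer-fold predictions.
#' @slot cvScores,cvLabels pooled outer-fold held-out scores and labels.
#' @slot freqTable data.frame (`feature`, `count`) of selection frequencies
#'   over the analysis folds.
#' @slot totalFolds repeats x outer x inner analysis folds.
#' @slot config the [rfeConfig()] used.
#'
#' @export
setClass("RFEModel",
  representation(forest = "ANY", selected = "character", bestSize = "numeric",
                 cvAUROC = "numeric", cvScores = "numeric",
                 cvLabels = "integer", freqTable = "data.frame",
                 totalFolds = "integer", config = "list"))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              class(object), d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "VOIMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VOIMask: %d x %d x %d voxels, %d foreground, spacing %s mm\n",
              d[1], d[2], d[3], sum(object@voxels),
              paste(format(object@spacing, digits = 3), collapse = " x ")))
})

setMethod("show", "LesionRegions", function(object) {
  cat(sprintf(paste0("LesionRegions (margin %.1f mm): tumor %d, ",
                     "dilated %d, rim %d voxels\n"),
              object@margin, sum(object@tumor@voxels),
              sum(object@dilated@voxels), sum(object@rim@voxels)))
})

setMethod("show", "PhantomCohort", function(object) {
  cat(sprintf("PhantomCohort: %d patients\n", nrow(object@clinical)))
  if (nrow(object@clinical) > 0) {
    cat("  subtypes:", paste(sprintf("%s=%d",
        names(table(object@clinical$subtype)),
        as.integer(table(object@clinical$subtype))), collapse = ", "), "\n")
  }
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport:\n")
  for (nm in names(object@stages)) {
    st <- object@stages[[nm]]
    cat(sprintf("  %-10s %d -> %d features\n", nm,
                length(st$features_in), length(st$features_out)))
  }
  cat(sprintf("  surviving: %d features\n", length(object@surviving)))
})

setMethod("show", "RFEModel", function(object) {
  cat(sprintf(paste0("RFEModel: %d selected features (best size %d), ",
                     "CV AUROC %.3f, %d analysis folds\n"),
              length(object@selected), object@bestSize, object@cvAUROC,
              object@totalFolds))
})

# ---- accessors -------------------------------------------------------------

#' @describeIn CTVolume-class intensity array accessor
#' @param x a `CTVolume` or `VOIMask`
#' @export
voxelData <- function(x) x@voxels

#' @describeIn CTVolume-class voxel spacing (mm) accessor
#' @export
voxelSpacing <- function(x) x@spacing

#' @describeIn CTVolume-class world origin (mm) accessor
#' @export
worldOrigin <- function(x) x@origin

#' @describeIn LesionRegions-class tumor mask accessor
#' @param regions a `LesionRegions`
#' @export
tumorMask <- function(regions) regions@tumor

#' @describeIn LesionRegions-class dilated mask accessor
#' @export
dilatedMask <- function(regions) regions@dilated

#' @describeIn LesionRegions-class peritumoral-rim mask accessor
#' @export
rimMask <- function(regions) regions@rim

#' @describeIn PhantomCohort-class clinical covariate table accessor
#' @param cohort a `PhantomCohort`
#' @export
clinicalData <- function(cohort) cohort@clinical

#' @describeIn PhantomCohort-class planted-effect registry accessor
#' @export
plantedRegistry <- function(cohort) cohort@registry

#' @describeIn SelectionReport-class surviving feature ids in rank order
#' @param report a `SelectionReport`
#' @export
survivingFeatures <- function(report) report@surviving

#' @describeIn SelectionReport-class per-stage details
#' @export
selectionStages <- function(report) report@stages

#' @describeIn RFEModel-class selected feature ids of the final forest
#' @param model an `RFEModel`
#' @export
selectedFeatures <- function(model) model@selected

#' @describeIn RFEModel-class selection-frequency table over analysis folds
#' @export
selectionFrequencies <- function(model) model@freqTable

#' @describeIn RFEModel-class cross-validated AUROC (pooled outer folds)
#' @export
cvAUROC <- function(model) model@cvAUROC

ctVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

voiMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "integer"
  new("VOIMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a CT volume object
#'
#' @param voxels 3D numeric array of intensities (HU).
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world coordinate of the first voxel center (mm).
#' @return a [CTVolume-class]
#' @export
CTVolume <- ctVolume

#' Construct a binary VOI mask object
#'
#' @param voxels 3D array coercible to 0/1.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world coordinate of the first voxel center (mm).
#' @return a [VOIMask-class]
#' @export
VOIMask <- voiMask
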
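#' Read a 3D CT volume from a NIfTI-1 file
#'
#' Spacing is taken from the NIfTI pixdim and the world origin from the
#' translation column of the stored affine.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing 3D scalar data.
#' @return a [CTVolume-class]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("unsupported format: expected 3D scalar data, got ",
         length(d), "D")
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- RNifti::xform(img)[1:3, 4]
  ctVolume(array(as.numeric(img), dim = d), spacing = spacing,
           origin = origin)
}

#' Read a binary VOI mask from a NIfTI-1 file
#'
#' @inheritParams readVolume
#' @return a [VOIMask-class]
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  voiMask(1L * (v@voxels > 0.5), spacing = v@spacing, origin = v@origin)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' @param volume a [CTVolume-class] or [VOIMask-class]
#' @param path output path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  dat <- volume@voxels
  if (is(volume, "VOIMask")) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  # qform stores only the rotation; voxel scale must go through pixdim
  RNifti::pixdim(img) <- volume@spacing
  aff <- diag(4)
  diag(aff)[1:3] <- volume@spacing
  aff[1:3, 4] <- volume@origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume/mask pair to an isotropic grid
#'
#' Intensities are resampled by trilinear interpolation, the mask by
#' nearest-neighbor, onto a grid of `target` mm cubic voxels covering the
#' input physical extent. Texture features are only comparable across lesions
#' on a common grid, so the whole pipeline runs at 1 mm^3 by default.
#'
#' @param volume a [CTVolume-class]
#' @param mask the aligned [VOIMask-class]
#' @param target isotropic voxel size in mm (> 0)
#' @return list with elements `volume` and `mask` on the new grid
#' @export
resampleIsotropic <- function(volume, mask, target = 1) {
  stopifnot(is(volume, "CTVolume"), is(mask, "VOIMask"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("target spacing must be a single positive value (mm)")
  if (!identical(dim(volume@voxels), dim(mask@voxels)))
    stop("volume and mask must share one grid")
  din <- dim(volume@voxels)
  sp <- volume@spacing
  dout <- pmax(as.integer(ceiling((din - 1) * sp / target)) + 1L, 1L)

  # continuous 0-based input index per output axis position
  cidx <- lapply(1:3, function(a) {
    pmin(pmax((seq_len(dout[a]) - 1) * target / sp[a], 0), din[a] - 1)
  })

  lo <- lapply(cidx, floor)
  fr <- Map(`-`, cidx, lo)
  hi <- Map(function(l, n) pmin(l + 1, n - 1), lo, din)

  g <- function(ix, iy, iz) {
    volume@voxels[cbind(
      rep(ix + 1, times = dout[2] * dout[3]),
      rep(rep(iy + 1, each = dout[1]), times = dout[3]),
      rep(iz + 1, each = dout[1] * dout[2]))]
  }
  wx <- rep(fr[[1]], times = dout[2] * dout[3])
  wy <- rep(rep(fr[[2]], each = dout[1]), times = dout[3])
  wz <- rep(fr[[3]], each = dout[1] * dout[2])
  vals <-
    g(lo[[1]], lo[[2]], lo[[3]]) * (1 - wx) * (1 - wy) * (1 - wz) +
    g(hi[[1]], lo[[2]], lo[[3]]) * wx       * (1 - wy) * (1 - wz) +
    g(lo[[1]], hi[[2]], lo[[3]]) * (1 - wx) * wy       * (1 - wz) +
    g(hi[[1]], hi[[2]], lo[[3]]) * wx       * wy       * (1 - wz) +
    g(lo[[1]], lo[[2]], hi[[3]]) * (1 - wx) * (1 - wy) * wz +
    g(hi[[1]], lo[[2]], hi[[3]]) * wx       * (1 - wy) * wz +
    g(lo[[1]], hi[[2]], hi[[3]]) * (1 - wx) * wy       * wz +
    g(hi[[1]], hi[[2]], hi[[3]]) * wx       * wy       * wz

  nn <- lapply(1:3, function(a) as.integer(round(cidx[[a]])) + 1L)
  mvals <- mask@voxels[cbind(
    rep(nn[[1]], times = dout[2] * dout[3]),
    rep(rep(nn[[2]], each = dout[1]), times = dout[3]),
    rep(nn[[3]], each = dout[1] * dout[2]))]

  list(
    volume = ctVolume(array(vals, dim = dout), spacing = rep(target, 3),
                      origin = volume@origin),
    mask = voiMask(array(mvals, dim = dout), spacing = rep(target, 3),
                   origin = mask@origin))
}

#' Euclidean distance (mm) from every voxel center to the nearest mask voxel
#'
#' @param mask a [VOIMask-class]
#' @return numeric array of distances in mm; 0 inside the mask
#' @export
distanceToMask <- function(mask) {
  stopifnot(is(mask, "VOIMask"))
  d2 <- cpp_edt_sq(as.logical(mask@voxels), dim(mask@voxels), mask@spacing)
  array(sqrt(d2), dim = dim(mask@voxels))
}

#' Dilate a mask by a physical margin
#'
#' Metric dilation: the output contains exactly the voxels whose center lies
#' within `margin` mm (Euclidean, via an exact distance transform) of some
#' foreground voxel center. This keeps "3 mm" a physical length on any grid,
#' including anisotropic ones.
#'
#' @param mask a non-empty [VOIMask-class]
#' @param margin dilation margin in mm (>= 0)
#' @return the dilated [VOIMask-class]
#' @export
dilateMask <- function(mask, margin) {
  stopifnot(is(mask, "VOIMask"))
  if (!is.numeric(margin) || length(margin) != 1L || margin < 0)
    stop("margin must be a single non-negative value (mm)")
  if (sum(mask@voxels) == 0) stop("empty mask cannot be dilated")
  d2 <- cpp_edt_sq(as.logical(mask@voxels), dim(mask@voxels), mask@spacing)
  out <- 1L * (array(d2, dim = dim(mask@voxels)) <= margin^2 + 1e-9)
  voiMask(out, spacing = mask@spacing, origin = mask@origin)
}

#' Build tumor, dilated and peritumoral-rim masks
#'
#' Expands the tumor VOI by `margin` mm and subtracts the tumor, leaving the
#' peritumoral rim that captures the invasive edge of the lesion and its
#' immediate environment.
#'
#' @param tumor a non-empty [VOIMask-class]
#' @param margin dilation margin in mm; 3 mm is the pipeline default
#' @return a [LesionRegions-class]
#' @export
makeRegions <- function(tumor, margin = 3) {
  dilated <- dilateMask(tumor, margin)
  rim <- voiMask(dilated@voxels - tumor@voxels, spacing = tumor@spacing,
                 origin = tumor@origin)
  if (sum(rim@voxels) == 0)
    warning("rim is empty: tumor reaches the grid boundary everywhere")
  new("LesionRegions", tumor = tumor, dilated = dilated, rim = rim,
      margin = margin)
}
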
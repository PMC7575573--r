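# 2D Gabor filter bank applied per axial slice. Kernels are complex
# (even/odd quadrature pair); the even part is made DC-free by subtracting a
# Gaussian-weighted offset, so a constant image gives zero magnitude.

gaborKernel <- function(theta_deg, wavelength_mm, spacing_mm, gamma = 1,
                        sigma_factor = 0.5, halfwidth_sigmas = 2.5) {
  sigma <- sigma_factor * wavelength_mm
  hw <- ceiling(halfwidth_sigmas * sigma / min(spacing_mm))
  ax <- (-hw:hw) * spacing_mm[1]
  ay <- (-hw:hw) * spacing_mm[2]
  x <- matrix(ax, length(ax), length(ay))
  y <- matrix(ay, length(ax), length(ay), byrow = TRUE)
  th <- theta_deg * pi / 180
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  gauss <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  even <- gauss * cos(2 * pi * xr / wavelength_mm)
  odd <- gauss * sin(2 * pi * xr / wavelength_mm)
  even <- even - gauss * sum(even) / sum(gauss)
  list(even = even, odd = odd)
}

# same-size 2D convolution via zero-padded FFT; kern may be complex
# (quadrature pair packed as even + i*odd), giving both responses in one pass
conv2same <- function(img, kern) {
  ni <- dim(img); nk <- dim(kern)
  np <- ni + nk - 1
  pi_ <- matrix(0, np[1], np[2]); pi_[1:ni[1], 1:ni[2]] <- img
  pk <- matrix(0 + 0i, np[1], np[2]); pk[1:nk[1], 1:nk[2]] <- kern
  full <- fft(fft(pi_) * fft(pk), inverse = TRUE) / prod(np)
  off <- (nk - 1) / 2
  full[off[1] + (1:ni[1]), off[2] + (1:ni[2])]
}

#' Gabor filter-bank edge features
#'
#' Oriented band-pass magnitude responses computed in 2D on each axial slice
#' (the in-plane CT resolution is where edge content lives), for a bank of
#' 4 orientations (0/45/90/135 degrees) x 2 wavelengths (4 and 8 mm). The
#' feature per bank element is the mean response magnitude over in-mask
#' voxels pooled across slices; slices that miss the mask are skipped.
#'
#' @inheritParams discretizeRegion
#' @param orientations orientations in degrees
#' @param wavelengths wavelengths in mm
#' @return named numeric vector, one feature per bank element
#' @export
gaborFeatures <- function(volume, mask, orientations = c(0, 45, 90, 135),
                          wavelengths = c(4, 8)) {
  stopifnot(is(volume, "CTVolume"), is(mask, "VOIMask"))
  if (sum(mask@voxels) == 0) stop("empty mask")
  dims <- dim(volume@voxels)
  zsel <- which(apply(mask@voxels, 3, sum) > 0)
  bank <- expand.grid(o = orientations, w = wavelengths)
  kerns <- lapply(seq_len(nrow(bank)), function(b) {
    k <- gaborKernel(bank$o[b], bank$w[b], volume@spacing[1:2])
    k$even + 1i * k$odd
  })
  # one shared zero-pad: image FFT computed once per slice, reused across
  # the whole bank
  nkmax <- max(vapply(kerns, nrow, integer(1)))
  np <- dims[1:2] + nkmax - 1
  kfft <- lapply(kerns, function(k) {
    pk <- matrix(0 + 0i, np[1], np[2])
    pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
    fft(pk)
  })
  offs <- lapply(kerns, function(k) (dim(k) - 1) / 2)
  acc <- matrix(0, nrow(bank), 2)  # running sum of |response| and count
  for (z in zsel) {
    sl <- volume@voxels[, , z]
    m <- mask@voxels[, , z] == 1L
    pi_ <- matrix(0, np[1], np[2])
    pi_[seq_len(dims[1]), seq_len(dims[2])] <- sl
    ifft <- fft(pi_)
    for (b in seq_len(nrow(bank))) {
      full <- fft(ifft * kfft[[b]], inverse = TRUE) / prod(np)
      resp <- full[offs[[b]][1] + seq_len(dims[1]),
                   offs[[b]][2] + seq_len(dims[2])]
      mag <- Mod(resp[m])
      acc[b, 1] <- acc[b, 1] + sum(mag)
      acc[b, 2] <- acc[b, 2] + length(mag)
    }
  }
  out <- acc[, 1] / acc[, 2]
  names(out) <- sprintf("gabor_o%d_w%g", bank$o, bank$w)
  out
}
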
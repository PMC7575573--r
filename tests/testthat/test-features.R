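strip_region <- function(levels) {
  # 1 x 1 x n strip packaged as a DiscretizedRegion
  lev <- array(as.integer(levels), dim = c(length(levels), 1, 1))
  as_region(lev, max(levels))
}

test_that("discretization maps intensities to 1..nBins by min-max binning", {
  d <- c(4, 4, 2)
  vol <- CTVolume(array(0:31, d))
  mask <- VOIMask(array(1L, d))
  reg <- discretizeRegion(vol, mask, 32)
  expect_identical(as.integer(reg$levels), 1:32)

  const <- discretizeRegion(CTVolume(array(5, c(3, 3, 3))),
                            VOIMask(array(1L, c(3, 3, 3))), 32)
  expect_true(all(const$levels == 1L))

  two <- CTVolume(array(rep(c(0, 10), each = 16), d))
  reg2 <- discretizeRegion(two, mask, 2)
  expect_setequal(unique(as.integer(reg2$levels)), c(1L, 2L))

  small <- VOIMask(array(c(rep(1L, 20), rep(0L, 12)), d))
  expect_error(discretizeRegion(vol, small, 32), "too small")
  expect_error(discretizeRegion(vol, mask, 1), "nBins")
})

test_that("first-order features match direct arithmetic", {
  v <- c(2, 4, 4, 4, 5, 5, 7, 9)
  vol <- CTVolume(array(v, c(8, 1, 1)))
  mask <- VOIMask(array(1L, c(8, 1, 1)))
  f <- firstOrderFeatures(vol, mask)
  expect_equal(unname(f["fo_mean"]), 5)
  expect_equal(unname(f["fo_variance"]), 4)  # population variance
  expect_equal(unname(f["fo_min"]), 2)
  expect_equal(unname(f["fo_max"]), 9)

  med <- firstOrderFeatures(CTVolume(array(1:4, c(4, 1, 1))),
                            VOIMask(array(1L, c(4, 1, 1))))
  expect_equal(unname(med["fo_median"]), 2.5)

  k <- firstOrderFeatures(CTVolume(array(7, c(3, 3, 3))),
                          VOIMask(array(1L, c(3, 3, 3))))
  expect_equal(unname(k["fo_variance"]), 0)
  expect_equal(unname(k["fo_skewness"]), 0)
  expect_equal(unname(k["fo_entropy"]), 0)
})

test_that("GLCM on a 1D strip matches hand-enumerated co-occurrence", {
  # levels [1,1,2,2]: symmetric pairs at distance 1 along the strip:
  # (1,1) x1, (1,2) x1, (2,2) x1 -> each counted both ways, total 6
  f <- glcmFeatures(strip_region(c(1, 1, 2, 2)))
  expect_equal(unname(f["glcm_contrast"]), 1 / 3)
  expect_equal(unname(f["glcm_joint_maximum"]), 1 / 3)
  expect_equal(unname(f["glcm_energy"]), (1 / 3)^2 * 2 + (1 / 6)^2 * 2)

  g <- glcmFeatures(as_region(array(1L, c(3, 3, 3)), 2))
  expect_equal(unname(g["glcm_contrast"]), 0)
  expect_equal(unname(g["glcm_energy"]), 1)
  expect_equal(unname(g["glcm_correlation"]), 0)  # zero-variance convention
})

test_that("GLRLM runs match hand enumeration", {
  # strip [1,1,1,2]: along the strip one run (1, len 3) and one (2, len 1);
  # 12 off-axis directions each see 4 unit runs
  f <- glrlmFeatures(strip_region(c(1, 1, 1, 2)))
  axis <- oracle_glrlm_stats(rbind(c(1, 3), c(2, 1)), 4, 2)
  unit <- oracle_glrlm_stats(rbind(c(1, 1), c(1, 1), c(1, 1), c(2, 1)), 4, 2)
  expect_equal(f, (axis + 12 * unit) / 13, tolerance = 1e-12)

  # constant strip of N voxels: one run of length N on the axis
  n <- 6
  g <- glrlmFeatures(strip_region(rep(1, n)))
  expect_equal(unname(g["glrlm_rp"]), (1 / n + 12 * 1) / 13)
})

test_that("GLSZM zones are 26-connected components", {
  lev <- array(0L, c(6, 3, 3))
  lev[1:2, 1, 1] <- 1L; lev[2, 2, 1] <- 1L           # zone of 3 (diagonal)
  lev[5:6, 1:2, 1] <- 1L; lev[5, 3, 2] <- 1L         # zone of 5
  f <- glszmFeatures(as_region(lev, 1))
  expect_equal(unname(f["glszm_sae"]), mean(c(1 / 9, 1 / 25)))
  expect_equal(unname(f["glszm_lae"]), mean(c(9, 25)))
  expect_equal(unname(f["glszm_zp"]), 2 / 8)
})

test_that("NGTDM degenerate region hits the coarseness convention", {
  f <- ngtdmFeatures(as_region(array(1L, c(3, 3, 3)), 2))
  expect_equal(unname(f["ngtdm_coarseness"]), 1e6)
  expect_equal(unname(f["ngtdm_contrast"]), 0)
})

test_that("all texture families equal naive-enumeration oracles on random
           regions", {
  for (s in 1:12) {
    lev <- random_region(s)
    reg <- as_region(lev, 8)
    expect_equal(glcmFeatures(reg), oracle_glcm_features(lev, 8),
                 tolerance = 1e-10)
    expect_equal(glrlmFeatures(reg), oracle_glrlm_features(lev, 8),
                 tolerance = 1e-10)
    expect_equal(glszmFeatures(reg), oracle_glszm_features(lev, 8),
                 tolerance = 1e-10)
    expect_equal(ngtdmFeatures(reg), oracle_ngtdm_features(lev, 8),
                 tolerance = 1e-10)
    expect_equal(ngldmFeatures(reg), oracle_ngldm_features(lev, 8),
                 tolerance = 1e-10)
  }
})

test_that("normalized matrices and analytic feature ranges hold", {
  for (s in 1:5) {
    lev <- random_region(100 + s)
    reg <- as_region(lev, 8)
    g <- glcmFeatures(reg)
    expect_gt(unname(g["glcm_energy"]), 0)
    expect_lte(unname(g["glcm_energy"]), 1)
    expect_gte(unname(g["glcm_joint_entropy"]), 0)
    r <- glrlmFeatures(reg)
    expect_gt(unname(r["glrlm_sre"]), 0)
    expect_lte(unname(r["glrlm_sre"]), 1)
    expect_lte(unname(r["glrlm_rp"]), 1)
  }
})

test_that("Gabor bank responds maximally at the matching orientation and
           wavelength and vanishes on constant input", {
  dims <- c(40, 40, 3)
  mask <- VOIMask(array(1L, dims))
  # interior mask keeps zero-padding edge effects out of the average
  inner <- array(0L, dims); inner[14:27, 14:27, ] <- 1L
  const <- gaborFeatures(CTVolume(array(100, dims)), VOIMask(inner))
  expect_true(all(const < 1e-8))

  # axial grating along x at 8 mm wavelength
  gr <- array(rep(sin(2 * pi * (1:40) / 8), times = 40 * 3), dims)
  f <- gaborFeatures(CTVolume(100 + 50 * gr), mask)
  expect_equal(names(which.max(f)), "gabor_o0_w8")

  # rotate the grating 90 degrees: the maximal element rotates with it
  gr90 <- aperm(gr, c(2, 1, 3))
  f90 <- gaborFeatures(CTVolume(100 + 50 * gr90), mask)
  expect_equal(names(which.max(f90)), "gabor_o90_w8")
  expect_equal(unname(f["gabor_o0_w8"]), unname(f90["gabor_o90_w8"]),
               tolerance = 1e-8)
})

test_that("the lesion vector honors the 200-feature manifest and the
           rim-difference identity", {
  expect_length(featureManifest("panel"), 100)
  expect_length(featureManifest("both"), 200)

  ph <- tiny_phantom(7, radius = 7)
  reg <- makeRegions(ph$mask, 3)
  fv <- extractLesionFeatures(ph$volume, reg)
  expect_length(fv, 200)
  expect_identical(names(fv), featureManifest("both"))
  expect_true(all(is.finite(fv)))
  expect_identical(sum(grepl("^intratumoral_", names(fv))), 100L)
  expect_identical(sum(grepl("^rim_", names(fv))), 100L)

  # rim_f + f(tumor) = f(dilated) exactly
  ft <- RimRadiomics:::computeRegionPanel(ph$volume, tumorMask(reg))
  fd <- RimRadiomics:::computeRegionPanel(ph$volume, dilatedMask(reg))
  expect_equal(unname(fv[paste0("rim_", names(ft))] + ft), unname(fd))

  # margin-0 regions give all-zero rim features
  reg0 <- suppressWarnings(makeRegions(ph$mask, 0))
  fv0 <- extractLesionFeatures(ph$volume, reg0)
  expect_true(all(fv0[grepl("^rim_", names(fv0))] == 0))
})

test_that("doubling intensities doubles the mean but leaves discretized
           texture invariant", {
  ph <- tiny_phantom(9, radius = 6)
  reg <- makeRegions(ph$mask, 3)
  f1 <- extractLesionFeatures(ph$volume, reg)
  v2 <- CTVolume(2 * voxelData(ph$volume), voxelSpacing(ph$volume))
  f2 <- extractLesionFeatures(v2, reg)
  expect_equal(f2["intratumoral_fo_mean"], 2 * f1["intratumoral_fo_mean"])
  tex <- grepl("^intratumoral_(glcm|glrlm|glszm|ngtdm|ngldm)_", names(f1))
  expect_equal(f1[tex], f2[tex], tolerance = 1e-10)
})
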
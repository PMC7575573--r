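#' Discretize intensities inside a region
#'
#' Within-mask min-max equal-width binning into `nBins` gray levels, the
#' prerequisite for all texture matrices. Constant regions map to level 1.
#' Regions below 27 voxels (a 3x3x3 neighborhood) are rejected: runs, zones
#' and neighborhoods are ill-defined on degenerate regions.
#'
#' @param volume a [CTVolume-class]
#' @param mask the aligned [VOIMask-class]
#' @param nBins number of gray levels (>= 2); default 32
#' @return a `DiscretizedRegion`: list with `levels` (integer array, 0 outside
#'   the mask), `nBins`, and `edges` (HU bin edges)
#' @export
discretizeRegion <- function(volume, mask, nBins = 32) {
  stopifnot(is(volume, "CTVolume"), is(mask, "VOIMask"))
  if (!identical(dim(volume@voxels), dim(mask@voxels)))
    stop("volume and mask must share one grid")
  if (nBins < 2) stop("nBins must be >= 2")
  inmask <- mask@voxels == 1L
  n <- sum(inmask)
  if (n < 27)
    stop("lesion too small: ", n, " voxels (< 27); texture undefined")
  x <- volume@voxels[inmask]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim = dim(volume@voxels))
  if (hi == lo) {
    lev[inmask] <- 1L
    edges <- c(lo, lo)
  } else {
    lev[inmask] <- pmin(as.integer(floor((x - lo) / (hi - lo) * nBins)) + 1L,
                        as.integer(nBins))
    edges <- seq(lo, hi, length.out = nBins + 1)
  }
  structure(list(levels = lev, nBins = as.integer(nBins), edges = edges),
            class = "DiscretizedRegion")
}

levelHistogram <- function(region) {
  lv <- region$levels[region$levels > 0L]
  tabulate(lv, nbins = region$nBins)
}

#' First-order intensity statistics
#'
#' The manifest's 19 first-order features: moments (population variance;
#' skewness and kurtosis defined as 0 on constant regions), energy, the
#' discretized-level entropy and uniformity, order statistics and robust
#' dispersion measures.
#'
#' @inheritParams discretizeRegion
#' @return named numeric vector of 19 features
#' @export
firstOrderFeatures <- function(volume, mask, nBins = 32) {
  stopifnot(is(volume, "CTVolume"), is(mask, "VOIMask"))
  x <- volume@voxels[mask@voxels == 1L]
  if (length(x) == 0) stop("empty mask")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else 0
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inr <- x[x >= q[1] & x <= q[5]]
  # entropy/uniformity bin inline: first-order statistics stay defined on
  # regions below the 27-voxel texture gate
  lev <- if (max(x) == min(x)) rep(1L, n) else
    pmin(as.integer(floor((x - min(x)) / (max(x) - min(x)) * nBins)) + 1L,
         as.integer(nBins))
  p <- tabulate(lev, nbins = as.integer(nBins)) / n
  pp <- p[p > 0]
  c(fo_mean = mu,
    fo_variance = m2,
    fo_skewness = skew,
    fo_kurtosis = kurt,
    fo_energy = sum(x^2),
    fo_entropy = -sum(pp * log2(pp)),
    fo_min = min(x),
    fo_max = max(x),
    fo_p10 = q[1], fo_p25 = q[2], fo_median = q[3], fo_p75 = q[4],
    fo_p90 = q[5],
    fo_iqr = q[4] - q[2],
    fo_range = max(x) - min(x),
    fo_mad = mean(abs(x - mu)),
    fo_rmad = mean(abs(inr - mean(inr))),
    fo_rms = sqrt(mean(x^2)),
    fo_uniformity = sum(p^2))
}

glcmFeaturesFromP <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  # i, j span the full grid, so grouping by |i-j| and i+j is always complete
  pd <- as.numeric(rowsum(c(p), c(abs(i - j)), reorder = TRUE))
  psum <- as.numeric(rowsum(c(p), c(i + j), reorder = TRUE))
  kd <- 0:(ng - 1); ksm <- 2:(2 * ng)
  da <- sum(kd * pd)
  sa <- sum(ksm * psum)
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  hxy <- ent(p)
  hx <- ent(px)
  pxy <- outer(px, px)
  ok <- p > 0 & pxy > 0
  hxy1 <- -sum(p[ok] * log2(pxy[ok]))
  offd <- i != j
  c(glcm_joint_maximum = max(p),
    glcm_joint_average = mu,
    glcm_joint_variance = sig2,
    glcm_joint_entropy = hxy,
    glcm_difference_average = da,
    glcm_difference_variance = sum((kd - da)^2 * pd),
    glcm_difference_entropy = ent(pd),
    glcm_sum_average = sa,
    glcm_sum_variance = sum((ksm - sa)^2 * psum),
    glcm_sum_entropy = ent(psum),
    glcm_energy = sum(p^2),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_inverse_difference = sum(p / (1 + abs(i - j))),
    glcm_inverse_difference_norm = sum(p / (1 + abs(i - j) / ng)),
    glcm_inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    glcm_inverse_difference_moment_norm = sum(p / (1 + (i - j)^2 / ng^2)),
    glcm_inverse_variance = sum(p[offd] / (i[offd] - j[offd])^2),
    glcm_correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0,
    glcm_autocorrelation = sum(i * j * p),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * p),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    glcm_info_correlation1 = if (hx > 0) (hxy - hxy1) / hx else 0)
}

#' Gray-level co-occurrence features
#'
#' Co-occurrence counted at Chebyshev distance 1 over the 13 unique 3D
#' directions; each direction's matrix is symmetrized and normalized, the 24
#' manifest statistics are computed per direction and averaged.
#'
#' @param region a `DiscretizedRegion` from [discretizeRegion()]
#' @return named numeric vector of 24 features
#' @export
glcmFeatures <- function(region) {
  ng <- region$nBins
  counts <- array(cpp_glcm(as.integer(region$levels), dim(region$levels), ng),
                  dim = c(ng, ng, 13))
  feats <- NULL
  used <- 0L
  for (d in 1:13) {
    tot <- sum(counts[, , d])
    if (tot == 0) next
    f <- glcmFeaturesFromP(counts[, , d] / tot)
    feats <- if (is.null(feats)) f else feats + f
    used <- used + 1L
  }
  if (used == 0L) stop("lesion too small: no co-occurring voxel pairs")
  feats / used
}

glrlmFeaturesFromR <- function(r, np) {
  ng <- nrow(r)
  i <- row(r); j <- col(r)
  nr <- sum(r)
  p <- r / nr
  ri <- rowSums(r); rj <- colSums(r)
  mui <- sum(i * p); muj <- sum(j * p)
  pp <- p[p > 0]
  c(glrlm_sre = sum(r / j^2) / nr,
    glrlm_lre = sum(r * j^2) / nr,
    glrlm_lglre = sum(r / i^2) / nr,
    glrlm_hglre = sum(r * i^2) / nr,
    glrlm_srlgle = sum(r / (i^2 * j^2)) / nr,
    glrlm_srhgle = sum(r * i^2 / j^2) / nr,
    glrlm_lrlgle = sum(r * j^2 / i^2) / nr,
    glrlm_lrhgle = sum(r * (i * j)^2) / nr,
    glrlm_gln = sum(ri^2) / nr,
    glrlm_glnn = sum(ri^2) / nr^2,
    glrlm_rln = sum(rj^2) / nr,
    glrlm_rlnn = sum(rj^2) / nr^2,
    glrlm_rp = nr / np,
    glrlm_glv = sum(p * (i - mui)^2),
    glrlm_rlv = sum(p * (j - muj)^2),
    glrlm_re = -sum(pp * log2(pp)))
}

#' Gray-level run-length features
#'
#' Maximal same-level runs per the 13 unique 3D directions; the 16 manifest
#' statistics are computed per direction and averaged.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 16 features
#' @export
glrlmFeatures <- function(region) {
  ng <- region$nBins
  dims <- dim(region$levels)
  maxlen <- max(dims)
  np <- sum(region$levels > 0L)
  counts <- array(cpp_glrlm(as.integer(region$levels), dims, ng),
                  dim = c(ng, maxlen, 13))
  feats <- NULL
  for (d in 1:13) {
    f <- glrlmFeaturesFromR(matrix(counts[, , d], ng, maxlen), np)
    feats <- if (is.null(feats)) f else feats + f
  }
  feats / 13
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level; a single matrix per
#' region (size zones carry no direction).
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 16 features
#' @export
glszmFeatures <- function(region) {
  zones <- cpp_glszm(as.integer(region$levels), dim(region$levels))
  np <- sum(region$levels > 0L)
  i <- zones[, 1]; j <- zones[, 2]
  nz <- nrow(zones)
  p_il <- tapply(rep(1, nz), factor(i, levels = 1:region$nBins), sum,
                 default = 0)
  p_sz <- tapply(rep(1, nz), factor(j, levels = 1:max(j)), sum, default = 0)
  pr <- 1 / nz
  mui <- mean(i); muj <- mean(j)
  # every zone is a distinct cell unless level/size coincide; aggregate
  key <- paste(i, j)
  celln <- as.numeric(table(key)) / nz
  c(glszm_sae = sum(1 / j^2) / nz,
    glszm_lae = sum(j^2) / nz,
    glszm_lglze = sum(1 / i^2) / nz,
    glszm_hglze = sum(i^2) / nz,
    glszm_salgle = sum(1 / (i^2 * j^2)) / nz,
    glszm_sahgle = sum(i^2 / j^2) / nz,
    glszm_lalgle = sum(j^2 / i^2) / nz,
    glszm_lahgle = sum((i * j)^2) / nz,
    glszm_gln = sum(p_il^2) / nz,
    glszm_glnn = sum(p_il^2) / nz^2,
    glszm_szn = sum(p_sz^2) / nz,
    glszm_sznn = sum(p_sz^2) / nz^2,
    glszm_zp = nz / np,
    glszm_glv = mean((i - mui)^2),
    glszm_zv = mean((j - muj)^2),
    glszm_ze = -sum(celln * log2(celln)))
}

#' Neighborhood gray-tone difference features
#'
#' 26-neighborhoods at Chebyshev distance 1 with out-of-mask neighbors
#' excluded from the neighborhood average. Constant regions make the
#' coarseness denominator vanish; coarseness is then set to 1e6 so phantom
#' cohorts with flat lesions stay finite.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 5 features
#' @export
ngtdmFeatures <- function(region) {
  res <- cpp_ngtdm(as.integer(region$levels), dim(region$levels),
                   region$nBins)
  s <- res$s
  nvox <- res$n
  nv <- sum(nvox)
  p <- nvox / nv
  act <- which(p > 0)
  ngp <- length(act)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  if (ngp > 1) {
    ij <- expand.grid(i = act, j = act)
    pi_ <- p[ij$i]; pj <- p[ij$j]
    contrast <- (sum(pi_ * pj * (ij$i - ij$j)^2) / (ngp * (ngp - 1))) *
      (sum(s) / nv)
    busy_den <- sum(abs(ij$i * pi_ - ij$j * pj))
    busyness <- if (busy_den > 0) coars_den / busy_den else 0
    complexity <- sum(abs(ij$i - ij$j) *
                      (pi_ * s[ij$i] + pj * s[ij$j]) / (pi_ + pj)) / nv
    strength <- if (sum(s) > 0)
      sum((pi_ + pj) * (ij$i - ij$j)^2) / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Neighborhood gray-level dependence features
#'
#' Dependence of a voxel = number of its in-mask 26-neighbors with the same
#' gray level (coarseness parameter alpha = 0). The 12 manifest statistics
#' follow the size-zone formula pattern over the (level, dependence) matrix.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 12 features
#' @export
ngldmFeatures <- function(region) {
  m <- cpp_ngldm(as.integer(region$levels), dim(region$levels),
                 region$nBins, 0L)
  ns <- sum(m)
  i <- row(m); k <- col(m)  # k = dependence + 1
  p <- m / ns
  si <- rowSums(m); sk <- colSums(m)
  pp <- p[p > 0]
  c(ngldm_sde = sum(m / k^2) / ns,
    ngldm_lde = sum(m * k^2) / ns,
    ngldm_lgle = sum(m / i^2) / ns,
    ngldm_hgle = sum(m * i^2) / ns,
    ngldm_sdlgle = sum(m / (i^2 * k^2)) / ns,
    ngldm_sdhgle = sum(m * i^2 / k^2) / ns,
    ngldm_ldlgle = sum(m * k^2 / i^2) / ns,
    ngldm_ldhgle = sum(m * (i * k)^2) / ns,
    ngldm_gln = sum(si^2) / ns,
    ngldm_dn = sum(sk^2) / ns,
    ngldm_dnn = sum(sk^2) / ns^2,
    ngldm_de = -sum(pp * log2(pp)))
}
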
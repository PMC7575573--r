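# Naive enumeration oracles for the texture families, written as direct
# loops over voxels/pairs/zones, independent of the package's compiled
# matrix builders. Levels arrays use 0 for out-of-mask voxels.

oracle_dirs <- matrix(c(
  1, 0, 0,  0, 1, 0,  0, 0, 1,
  1, 1, 0,  1, -1, 0,  1, 0, 1,  1, 0, -1,  0, 1, 1,  0, 1, -1,
  1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1), ncol = 3, byrow = TRUE)

ovox <- function(lev, p) {
  d <- dim(lev)
  if (any(p < 1) || any(p > d)) return(0L)
  lev[p[1], p[2], p[3]]
}

oracle_glcm_features <- function(lev, ng) {
  inmask <- which(lev > 0, arr.ind = TRUE)
  acc <- NULL; used <- 0
  for (d in seq_len(nrow(oracle_dirs))) {
    off <- oracle_dirs[d, ]
    cm <- matrix(0, ng, ng)
    for (r in seq_len(nrow(inmask))) {
      a <- ovox(lev, inmask[r, ])
      b <- ovox(lev, inmask[r, ] + off)
      if (b > 0) {
        cm[a, b] <- cm[a, b] + 1
        cm[b, a] <- cm[b, a] + 1
      }
    }
    if (sum(cm) == 0) next
    p <- cm / sum(cm)
    f <- oracle_glcm_stats(p)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1
  }
  acc / used
}

oracle_glcm_stats <- function(p) {
  ng <- nrow(p)
  mu <- 0; for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  sig2 <- 0; for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  px <- rowSums(p)
  pd <- numeric(ng); psum <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
  }
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  da <- sum(kd * pd); sa <- sum(ks * psum)
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  hxy1 <- 0
  for (i in 1:ng) for (j in 1:ng)
    if (p[i, j] > 0 && px[i] * px[j] > 0)
      hxy1 <- hxy1 - p[i, j] * log2(px[i] * px[j])
  s <- function(expr) {
    tot <- 0
    for (i in 1:ng) for (j in 1:ng) tot <- tot + expr(i, j) * p[i, j]
    tot
  }
  iv <- 0
  for (i in 1:ng) for (j in 1:ng)
    if (i != j) iv <- iv + p[i, j] / (i - j)^2
  c(glcm_joint_maximum = max(p),
    glcm_joint_average = mu,
    glcm_joint_variance = sig2,
    glcm_joint_entropy = H(p),
    glcm_difference_average = da,
    glcm_difference_variance = sum((kd - da)^2 * pd),
    glcm_difference_entropy = H(pd),
    glcm_sum_average = sa,
    glcm_sum_variance = sum((ks - sa)^2 * psum),
    glcm_sum_entropy = H(psum),
    glcm_energy = sum(p^2),
    glcm_contrast = s(function(i, j) (i - j)^2),
    glcm_dissimilarity = s(function(i, j) abs(i - j)),
    glcm_inverse_difference = s(function(i, j) 1 / (1 + abs(i - j))),
    glcm_inverse_difference_norm = s(function(i, j) 1 / (1 + abs(i - j) / ng)),
    glcm_inverse_difference_moment = s(function(i, j) 1 / (1 + (i - j)^2)),
    glcm_inverse_difference_moment_norm =
      s(function(i, j) 1 / (1 + (i - j)^2 / ng^2)),
    glcm_inverse_variance = iv,
    glcm_correlation =
      if (sig2 > 0) (s(function(i, j) i * j) - mu^2) / sig2 else 0,
    glcm_autocorrelation = s(function(i, j) i * j),
    glcm_cluster_tendency = s(function(i, j) (i + j - 2 * mu)^2),
    glcm_cluster_shade = s(function(i, j) (i + j - 2 * mu)^3),
    glcm_cluster_prominence = s(function(i, j) (i + j - 2 * mu)^4),
    glcm_info_correlation1 =
      if (H(px) > 0) (H(p) - hxy1) / H(px) else 0)
}

oracle_runs <- function(lev, off) {
  runs <- list()
  inmask <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(inmask))) {
    p <- inmask[r, ]
    a <- ovox(lev, p)
    if (ovox(lev, p - off) == a) next  # not a run start
    len <- 1
    while (ovox(lev, p + len * off) == a) len <- len + 1
    runs[[length(runs) + 1]] <- c(a, len)
  }
  do.call(rbind, runs)
}

oracle_glrlm_stats <- function(runs, np, ng) {
  i <- runs[, 1]; j <- runs[, 2]
  nr <- nrow(runs)
  ri <- vapply(1:ng, function(l) sum(i == l), numeric(1))
  rj <- vapply(1:max(j), function(l) sum(j == l), numeric(1))
  mui <- mean(i); muj <- mean(j)
  cellp <- as.numeric(table(paste(i, j))) / nr
  c(glrlm_sre = mean(1 / j^2), glrlm_lre = mean(j^2),
    glrlm_lglre = mean(1 / i^2), glrlm_hglre = mean(i^2),
    glrlm_srlgle = mean(1 / (i * j)^2), glrlm_srhgle = mean(i^2 / j^2),
    glrlm_lrlgle = mean(j^2 / i^2), glrlm_lrhgle = mean((i * j)^2),
    glrlm_gln = sum(ri^2) / nr, glrlm_glnn = sum(ri^2) / nr^2,
    glrlm_rln = sum(rj^2) / nr, glrlm_rlnn = sum(rj^2) / nr^2,
    glrlm_rp = nr / np,
    glrlm_glv = mean((i - mui)^2), glrlm_rlv = mean((j - muj)^2),
    glrlm_re = -sum(cellp * log2(cellp)))
}

oracle_glrlm_features <- function(lev, ng) {
  np <- sum(lev > 0)
  acc <- NULL
  for (d in seq_len(nrow(oracle_dirs))) {
    runs <- oracle_runs(lev, oracle_dirs[d, ])
    f <- oracle_glrlm_stats(runs, np, ng)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(oracle_dirs)
}

oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  idx <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    a <- ovox(lev, p0)
    queue <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == a) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(lev, ng) {
  z <- oracle_zones(lev)
  np <- sum(lev > 0)
  i <- z[, 1]; j <- z[, 2]
  nz <- nrow(z)
  pi_ <- vapply(1:ng, function(l) sum(i == l), numeric(1))
  pj <- vapply(1:max(j), function(l) sum(j == l), numeric(1))
  cellp <- as.numeric(table(paste(i, j))) / nz
  c(glszm_sae = mean(1 / j^2), glszm_lae = mean(j^2),
    glszm_lglze = mean(1 / i^2), glszm_hglze = mean(i^2),
    glszm_salgle = mean(1 / (i * j)^2), glszm_sahgle = mean(i^2 / j^2),
    glszm_lalgle = mean(j^2 / i^2), glszm_lahgle = mean((i * j)^2),
    glszm_gln = sum(pi_^2) / nz, glszm_glnn = sum(pi_^2) / nz^2,
    glszm_szn = sum(pj^2) / nz, glszm_sznn = sum(pj^2) / nz^2,
    glszm_zp = nz / np,
    glszm_glv = mean((i - mean(i))^2), glszm_zv = mean((j - mean(j))^2),
    glszm_ze = -sum(cellp * log2(cellp)))
}

oracle_neighbors <- function(lev, p) {
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  out <- integer(0)
  for (k in seq_len(nrow(nb))) {
    v <- ovox(lev, p + nb[k, ])
    if (v > 0) out <- c(out, v)
  }
  out
}

oracle_ngtdm_features <- function(lev, ng) {
  idx <- which(lev > 0, arr.ind = TRUE)
  s <- numeric(ng); n <- numeric(ng)
  for (r in seq_len(nrow(idx))) {
    a <- ovox(lev, idx[r, ])
    nbv <- oracle_neighbors(lev, idx[r, ])
    if (length(nbv) == 0) next
    s[a] <- s[a] + abs(a - mean(nbv))
    n[a] <- n[a] + 1
  }
  nv <- sum(n); p <- n / nv
  act <- which(p > 0); ngp <- length(act)
  den <- sum(p * s)
  coarse <- if (den > 0) 1 / den else 1e6
  contrast <- busy <- complexity <- strength <- 0
  if (ngp > 1) {
    for (i in act) for (j in act) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      busy <- busy + abs(i * p[i] - j * p[j])
      complexity <- complexity +
        abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / nv
    busy <- if (busy > 0) den / busy else 0
    complexity <- complexity / nv
    strength <- if (sum(s) > 0) strength / sum(s) else 0
  }
  c(ngtdm_coarseness = coarse, ngtdm_contrast = contrast,
    ngtdm_busyness = busy, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

oracle_ngldm_features <- function(lev, ng) {
  idx <- which(lev > 0, arr.ind = TRUE)
  rows <- matrix(0, nrow(idx), 2)
  for (r in seq_len(nrow(idx))) {
    a <- ovox(lev, idx[r, ])
    nbv <- oracle_neighbors(lev, idx[r, ])
    rows[r, ] <- c(a, sum(nbv == a) + 1)  # k = dependence + 1
  }
  i <- rows[, 1]; k <- rows[, 2]
  ns <- nrow(rows)
  si <- vapply(1:ng, function(l) sum(i == l), numeric(1))
  sk <- vapply(1:27, function(l) sum(k == l), numeric(1))
  cellp <- as.numeric(table(paste(i, k))) / ns
  c(ngldm_sde = mean(1 / k^2), ngldm_lde = mean(k^2),
    ngldm_lgle = mean(1 / i^2), ngldm_hgle = mean(i^2),
    ngldm_sdlgle = mean(1 / (i * k)^2), ngldm_sdhgle = mean(i^2 / k^2),
    ngldm_ldlgle = mean(k^2 / i^2), ngldm_ldhgle = mean((i * k)^2),
    ngldm_gln = sum(si^2) / ns,
    ngldm_dn = sum(sk^2) / ns, ngldm_dnn = sum(sk^2) / ns^2,
    ngldm_de = -sum(cellp * log2(cellp)))
}

# random discretized test region: dims up to maxdim^3, levels 1..ng with 0
# holes outside a random mask
random_region <- function(seed, maxdim = 6, ng = 8, density = 0.8) {
  set.seed(seed)
  d <- sample(3:maxdim, 3, replace = TRUE)
  lev <- array(sample(0:ng, prod(d), replace = TRUE,
                      prob = c(1 - density, rep(density / ng, ng))), dim = d)
  if (sum(lev > 0) < 2) lev[1:2] <- c(1L, 2L)
  storage.mode(lev) <- "integer"
  lev
}

as_region <- function(lev, ng) {
  structure(list(levels = lev, nBins = as.integer(ng),
                 edges = seq(0, 1, length.out = ng + 1)),
            class = "DiscretizedRegion")
}

# small phantom fixture shared across tests
tiny_phantom <- function(seed = 42, radius = 8) {
  generatePhantom(radii = rep(radius, 3), seed = seed)
}
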
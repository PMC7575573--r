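#' Scanner-stability filter (Kruskal-Wallis)
#'
#' Removes radiomic features that vary significantly across CT scanner
#' manufacturers: a cheap harmonization step that drops batch-confounded
#' features instead of modeling the batch. With a single manufacturer group
#' (or groups below 3 lesions) the filter is skipped with a warning and all
#' features are retained.
#'
#' @param x numeric matrix, lesions x features
#' @param scanner per-lesion manufacturer labels
#' @param alpha removal threshold on the Kruskal-Wallis p-value
#'   (uncorrected; an aggressive filter is the conservative harmonization
#'   choice)
#' @return stage list with `features_in`, `features_out`, `scores`
#'   (p-values; `NA` for constant features, which are retained)
#' @export
stabilityFilter <- function(x, scanner, alpha = 0.05) {
  stopifnot(is.matrix(x), nrow(x) == length(scanner))
  grp <- factor(scanner)
  tab <- table(grp)
  feats <- colnames(x)
  if (length(tab) < 2 || sum(tab >= 3) < 2) {
    warning("stability filter skipped: need >= 2 scanner groups with >= 3 ",
            "lesions each")
    return(list(features_in = feats, features_out = feats,
                scores = stats::setNames(rep(NA_real_, length(feats)),
                                         feats)))
  }
  p <- vapply(feats, function(f) {
    v <- x[, f]
    if (length(unique(v)) < 2) return(NA_real_)  # no variation to test
    kruskal.test(v, grp)$p.value
  }, numeric(1))
  keep <- is.na(p) | p >= alpha
  list(features_in = feats, features_out = feats[keep], scores = p)
}

miBin3 <- function(v) {
  # 3 equal-frequency bins; degrades gracefully for heavily tied features
  q <- unique(quantile(v, c(1 / 3, 2 / 3), names = FALSE))
  findInterval(v, q, left.open = TRUE)
}

mutualInformation <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  ok <- p > 0
  sum(p[ok] * log(p[ok] / e[ok]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR in the difference (MID) form: each step adds the feature
#' maximizing MI(f; y) - mean MI(f; s) over already-selected features s,
#' with mutual information estimated on 3 equal-frequency bins. Ties break
#' lexicographically on feature id, making the ranking deterministic.
#'
#' @param x numeric matrix, lesions x features (>= 2 features)
#' @param y binary labels (0/1), both classes present
#' @param fraction proportion of features to retain, in (0, 1];
#'   `ceiling(fraction * n)` features are returned in rank order
#' @return stage list with `features_in`, `features_out` (rank order),
#'   `scores` (the mRMR score at the step each feature was selected)
#' @export
mrmrSelect <- function(x, y, fraction = 0.8) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (length(unique(y)) < 2) stop("both classes must be present")
  feats <- colnames(x)
  k <- as.integer(ceiling(fraction * length(feats)))
  binned <- apply(x, 2, miBin3)
  rel <- vapply(feats, function(f) mutualInformation(binned[, f], y),
                numeric(1))
  selected <- character(0)
  scores <- numeric(0)
  # cache pairwise MI against selected features as we go
  red_sum <- stats::setNames(rep(0, length(feats)), feats)
  remaining <- feats
  for (step in seq_len(k)) {
    sc <- rel[remaining] -
      if (length(selected)) red_sum[remaining] / length(selected) else 0
    best <- remaining[order(-sc, remaining)][1]
    selected <- c(selected, best)
    scores <- c(scores, sc[[best]])
    remaining <- setdiff(remaining, best)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(f)
          mutualInformation(binned[, f], binned[, best]), numeric(1))
  }
  list(features_in = feats, features_out = selected,
       scores = stats::setNames(scores, selected))
}

upsampleIdx <- function(y) {
  # balance classes by resampling the minority class with replacement
  tab <- table(y)
  if (length(tab) < 2 || tab[1] == tab[2]) return(seq_along(y))
  minor <- names(tab)[which.min(tab)]
  extra <- sample(which(y == minor), max(tab) - min(tab), replace = TRUE)
  c(seq_along(y), extra)
}

stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Elastic-net prefilter
#'
#' Penalized logistic regression tuned over a (alpha, lambda) grid by
#' repeated stratified 5-fold cross-validation with the minority class
#' upsampled with replacement inside training folds only. The penalty is
#' tuned by the one-standard-error rule: the strongest penalty whose mean
#' cross-validated deviance sits within one standard error of the minimum.
#' Importance of a feature is the mean absolute standardized coefficient at
#' the selected hyperparameters across repeats; features with importance > 0
#' survive.
#'
#' @param x numeric matrix, lesions x features
#' @param y binary labels (0/1)
#' @param folds,repeats cross-validation layout (default 5 x 10)
#' @param upsample balance classes inside training folds
#' @param alphas elastic-net mixing values searched
#' @param seed RNG seed for fold assignment and upsampling
#' @return stage list with `features_in`, `features_out`, `scores`
#'   (importances), `alpha`, `lambda`
#' @export
prefilterElasticNet <- function(x, y, folds = 5, repeats = 10,
                                upsample = TRUE,
                                alphas = c(0.1, 0.55, 1), seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  set.seed(seed)
  y <- as.integer(y)
  feats <- colnames(x)
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  # common lambda path per alpha from the full data
  paths <- lapply(alphas, function(a)
    glmnet::glmnet(xs, y, family = "binomial", alpha = a,
                   standardize = FALSE, nlambda = 40)$lambda)
  dev <- lapply(paths, function(l) matrix(0, length(l), 0))
  foldsets <- replicate(repeats, stratifiedFolds(y, folds),
                        simplify = FALSE)
  for (r in seq_len(repeats)) {
    fold <- foldsets[[r]]
    for (fd in seq_len(folds)) {
      tr <- which(fold != fd); te <- which(fold == fd)
      idx <- if (upsample) tr[upsampleIdx(y[tr])] else tr
      for (ai in seq_along(alphas)) {
        fit <- tryCatch(
          glmnet::glmnet(xs[idx, , drop = FALSE], y[idx],
                         family = "binomial", alpha = alphas[ai],
                         standardize = FALSE, lambda = paths[[ai]]),
          error = function(e) NULL)
        if (is.null(fit)) next
        pr <- predict(fit, xs[te, , drop = FALSE], type = "response",
                      s = paths[[ai]])
        eps <- 1e-12
        d <- -2 * colMeans(y[te] * log(pmax(pr, eps)) +
                           (1 - y[te]) * log(pmax(1 - pr, eps)))
        dev[[ai]] <- cbind(dev[[ai]], d)
      }
    }
  }
  mean_dev <- lapply(dev, rowMeans)
  best_ai <- which.min(vapply(mean_dev, min, numeric(1)))
  # one-standard-error rule: strongest penalty whose CV deviance is within
  # one SE of the minimum, so null features are pruned aggressively
  md <- mean_dev[[best_ai]]
  imin <- which.min(md)
  se_min <- sd(dev[[best_ai]][imin, ]) / sqrt(ncol(dev[[best_ai]]))
  best_lambda <- max(paths[[best_ai]][md <= md[imin] + se_min])
  # importance across repeats at the tuned hyperparameters
  imp <- matrix(0, length(feats), repeats, dimnames = list(feats, NULL))
  for (r in seq_len(repeats)) {
    idx <- if (upsample) upsampleIdx(y) else seq_along(y)
    fit <- tryCatch(
      glmnet::glmnet(xs[idx, , drop = FALSE], y[idx], family = "binomial",
                     alpha = alphas[best_ai], standardize = FALSE,
                     lambda = paths[[best_ai]]),
      error = function(e) NULL)
    if (is.null(fit)) {
      # separation fallback: strongest penalty on the path
      imp[, r] <- 0
      warning("elastic-net fit failed in repeat ", r,
              "; strongest-penalty fallback (no importance)")
      next
    }
    cf <- as.matrix(predict(fit, type = "coefficients", s = best_lambda))
    imp[, r] <- abs(cf[feats, 1])
  }
  importance <- rowMeans(imp)
  keep <- feats[importance > 0]
  list(features_in = feats, features_out = keep, scores = importance,
       alpha = alphas[best_ai], lambda = best_lambda)
}

#' Z-score standardization with stored training parameters
#'
#' Centers and scales every column to mean 0, sd 1 (sample sd) using
#' training-set parameters only; a held-out table is transformed with the
#' stored parameters, never its own, so no information leaks across the
#' split. Zero-variance training columns pass through as all zeros with a
#' warning.
#'
#' @param train numeric matrix, lesions x features
#' @param apply_to optional matrix with the same columns to transform with
#'   the training parameters
#' @return list with `train`, `applied` (or `NULL`), `center`, `scale`
#' @export
zscoreStandardize <- function(train, apply_to = NULL) {
  stopifnot(is.matrix(train))
  if (!is.null(apply_to) &&
      !identical(colnames(train), colnames(apply_to)))
    stop("column sets of train and apply_to must match")
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    warning(sum(zero), " constant column(s) standardized to 0")
    scl[zero] <- 1
  }
  tf <- function(m) {
    out <- sweep(sweep(m, 2, ctr, `-`), 2, scl, `/`)
    out[, zero] <- 0
    out
  }
  list(train = tf(train),
       applied = if (is.null(apply_to)) NULL else tf(apply_to),
       center = ctr, scale = scl)
}

#' Run the three-stage feature-selection cascade
#'
#' Stability filter (scanner Kruskal-Wallis), then mRMR top-`fraction`
#' ranking, then the elastic-net prefilter — applied in that order on the
#' discovery split only. Clinical covariates never enter the cascade; they
#' are appended to the surviving radiomic features before classification.
#'
#' @param x numeric matrix of radiomic features, lesions x features
#' @param y binary labels (0/1)
#' @param scanner per-lesion manufacturer labels
#' @param alpha stability-filter significance level
#' @param mrmrFraction proportion retained by mRMR
#' @param folds,repeats,upsample elastic-net prefilter settings
#' @param seed RNG seed for the prefilter
#' @return a [SelectionReport-class]
#' @export
runSelectionCascade <- function(x, y, scanner, alpha = 0.05,
                                mrmrFraction = 0.8, folds = 5, repeats = 10,
                                upsample = TRUE, seed = 1L) {
  st1 <- stabilityFilter(x, scanner, alpha)
  x1 <- x[, st1$features_out, drop = FALSE]
  st2 <- mrmrSelect(x1, y, mrmrFraction)
  x2 <- x1[, st2$features_out, drop = FALSE]
  st3 <- prefilterElasticNet(x2, y, folds = folds, repeats = repeats,
                             upsample = upsample, seed = seed)
  surv <- st2$features_out[st2$features_out %in% st3$features_out]
  new("SelectionReport",
      stages = list(stability = st1, mrmr = st2, prefilter = st3),
      surviving = surv)
}
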
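#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) pairs where the positive scores higher,
#' ties counted 1/2 — the normalized Mann-Whitney U statistic.
#'
#' @param scores numeric classifier scores
#' @param labels binary labels (0/1); both classes must be present
#' @return AUROC in [0, 1]
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: one class absent")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values: for each case, the AUROC of its score against the other
# class (DeLong's V10 / V01 components)
placementValues <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                numeric(1))
  list(v10 = v10, v01 = v01)
}

delongVariance <- function(scores, labels) {
  pv <- placementValues(scores, labels)
  m <- length(pv$v10); n <- length(pv$v01)
  # var of the empirical AUROC from the placement-value covariances
  s10 <- if (m > 1) var(pv$v10) else 0
  s01 <- if (n > 1) var(pv$v01) else 0
  s10 / m + s01 / n
}

#' DeLong confidence intervals and unpaired AUROC comparison
#'
#' Computes each sample's AUROC with a DeLong placement-value variance and
#' Wald 95% CI truncated to [0, 1], and tests the AUROC difference between
#' two independent cohorts (e.g. training cross-validation vs held-out test)
#' with a two-sided z-test on the summed variances.
#'
#' @param scores_a,labels_a first sample (scores, 0/1 labels)
#' @param scores_b,labels_b second sample
#' @param conf confidence level
#' @return list with `auc_a`, `ci_a`, `auc_b`, `ci_b`, `p`
#' @export
delongTest <- function(scores_a, labels_a, scores_b, labels_b,
                       conf = 0.95) {
  a <- auroc(scores_a, labels_a)
  b <- auroc(scores_b, labels_b)
  va <- delongVariance(scores_a, labels_a)
  vb <- delongVariance(scores_b, labels_b)
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- function(auc, v) pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
  vsum <- va + vb
  if (vsum <= 0) {
    warning("degenerate DeLong variance (AUROC at 0 or 1); p set to NA")
    p <- NA_real_
  } else {
    p <- 2 * pnorm(-abs(a - b) / sqrt(vsum))
  }
  list(auc_a = a, ci_a = ci(a, va), auc_b = b, ci_b = ci(b, vb), p = p)
}

#' Confusion-matrix metrics with exact confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV from the 2x2 table, each with a
#' Clopper-Pearson exact 95% CI. Empty denominators (e.g. no predicted
#' positives for PPV) give `NA` with a warning.
#'
#' @param predicted,truth binary 0/1 vectors of equal length
#' @param conf confidence level
#' @return data.frame with `metric`, `estimate`, `lower`, `upper`
#' @export
confusionMetrics <- function(predicted, truth, conf = 0.95) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  tp <- sum(predicted == 1 & truth == 1)
  fn <- sum(predicted == 0 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  one <- function(num, den, metric) {
    if (den == 0) {
      warning(metric, " undefined: empty denominator")
      return(data.frame(metric = metric, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    }
    ci <- binom.test(num, den, conf.level = conf)$conf.int
    data.frame(metric = metric, estimate = num / den,
               lower = ci[1], upper = ci[2])
  }
  rbind(one(tp, tp + fn, "sensitivity"),
        one(tn, tn + fp, "specificity"),
        one(tp, tp + fp, "ppv"),
        one(tn, tn + fn, "npv"))
}

mannWhitneyOne <- function(a, b) {
  if (length(unique(c(a, b))) < 2) return(c(U = length(a) * length(b) / 2,
                                            p = 1))
  exact <- length(a) < 8 || length(b) < 8
  if (exact && any(duplicated(c(a, b)))) exact <- FALSE
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact))
  c(U = unname(wt$statistic), p = wt$p.value)
}

#' Mann-Whitney feature associations with Benjamini-Hochberg correction
#'
#' Two-sided Mann-Whitney U per feature between the classes (exact
#' enumeration when both groups are below 8 and untied, normal approximation
#' with tie correction otherwise), then BH step-up adjustment across the
#' feature set. Constant features get p = 1 by convention.
#'
#' @param x numeric matrix of the relevant features, lesions x features
#' @param y binary labels (0/1)
#' @return data.frame with `feature`, `U`, `p`, `p_adj` ordered as the input
#'   columns
#' @export
mannWhitneyBH <- function(x, y) {
  stopifnot(is.matrix(x), ncol(x) >= 1)
  y <- as.integer(y)
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    stop("both classes need >= 1 sample")
  res <- t(vapply(colnames(x), function(f)
    mannWhitneyOne(x[y == 1, f], x[y == 0, f]), numeric(2)))
  data.frame(feature = colnames(x), U = res[, 1], p = res[, 2],
             p_adj = p.adjust(res[, 2], method = "BH"), row.names = NULL)
}

#' Evaluate a fitted model on a cohort
#'
#' Assembles the full evaluation report: AUROC with DeLong CI, confusion
#' metrics at the 0.5 operating point with Clopper-Pearson CIs, the unpaired
#' DeLong comparison of training cross-validated vs held-out AUROC, and
#' BH-corrected Mann-Whitney associations of the relevant features.
#'
#' @param model an [RFEModel-class]
#' @param x standardized held-out matrix
#' @param y held-out binary labels
#' @param xAll optional matrix (all lesions of the evaluation cohort) for
#'   the per-relevant-feature association tests; defaults to `x`
#' @param yAll labels matching `xAll`
#' @param threshold operating point for hard labels
#' @return list of class `EvaluationReport`
#' @export
evaluateModel <- function(model, x, y, xAll = x, yAll = y,
                          threshold = 0.5) {
  scores <- predictScores(model, x)
  dl <- delongTest(model@cvScores, model@cvLabels, scores, y)
  cm <- confusionMetrics(as.integer(scores > threshold), y)
  rel <- relevantFeatures(model)
  assoc <- if (length(rel))
    mannWhitneyBH(xAll[, rel, drop = FALSE], yAll) else NULL
  structure(list(
    cv_auroc = dl$auc_a, cv_auroc_ci = dl$ci_a,
    test_auroc = dl$auc_b, test_auroc_ci = dl$ci_b,
    delong_p = dl$p,
    confusion = cm,
    relevant_features = rel,
    associations = assoc,
    n_train = length(model@cvLabels) / model@config$repeats,
    n_test = length(y)),
    class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("Training (CV) AUROC %.2f (%.2f, %.2f)\n",
              x$cv_auroc, x$cv_auroc_ci[1], x$cv_auroc_ci[2]))
  cat(sprintf("Test AUROC          %.2f (%.2f, %.2f)   DeLong p = %s\n",
              x$test_auroc, x$test_auroc_ci[1], x$test_auroc_ci[2],
              format.pval(x$delong_p, digits = 2)))
  cm <- x$confusion
  for (i in seq_len(nrow(cm)))
    cat(sprintf("  %-12s %.2f (%.2f, %.2f)\n", cm$metric[i],
                cm$estimate[i], cm$lower[i], cm$upper[i]))
  cat(sprintf("Relevant features: %d\n", length(x$relevant_features)))
  invisible(x)
}
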
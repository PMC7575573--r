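#' Configuration for the RFE random forest
#'
#' The printed study configuration is 2000 trees with repeated (n = 10)
#' five-fold nested cross-validation: 10 repeats x 5 outer folds x 5 inner
#' folds = 250 analysis folds. Candidate subset sizes follow a geometric
#' grid plus "all features".
#'
#' @param nTrees trees per forest (2000 default; structural checks are valid
#'   at smaller counts)
#' @param repeats outer repeats
#' @param outerFolds,innerFolds nested cross-validation layout
#' @param subsetSizes candidate feature-subset sizes; `NULL` means
#'   \{2, 4, 8, 16, 32, all\} clipped to the feature count
#' @param seed master seed; per-repeat/per-fold seeds are derived from it
#' @return config list of class `RFEConfig`
#' @export
rfeConfig <- function(nTrees = 2000, repeats = 10, outerFolds = 5,
                      innerFolds = 5, subsetSizes = NULL, seed = 1L) {
  if (outerFolds < 2 || innerFolds < 2) stop("folds must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")
  structure(list(nTrees = as.integer(nTrees), repeats = as.integer(repeats),
                 outerFolds = as.integer(outerFolds),
                 innerFolds = as.integer(innerFolds),
                 subsetSizes = subsetSizes, seed = as.integer(seed)),
            class = "RFEConfig")
}

# stratified folds where every held-out fold keeps both classes; re-draws on
# failure, errors when the class balance cannot support the layout
validFolds <- function(y, k, tries = 25) {
  for (t in seq_len(tries)) {
    fold <- stratifiedFolds(y, k)
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) == 2 &&
        length(unique(y[fold != f])) == 2, logical(1)))
    if (ok) return(fold)
  }
  stop("cannot stratify: a fold is single-class after repeated re-draws")
}

fitForest <- function(x, y, nTrees, seed, importance = "none") {
  tab <- table(factor(y, levels = c(0, 1)))
  w <- as.numeric(sum(tab) / (2 * tab))
  ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                 num.trees = nTrees, probability = TRUE,
                 importance = importance, class.weights = w,
                 seed = seed, num.threads = 1)
}

forestScores <- function(fit, x) {
  predict(fit, data = x, num.threads = 1)$predictions[, "1"]
}

rankByImportance <- function(x, y, nTrees, seed) {
  fit <- fitForest(x, y, nTrees, seed, importance = "impurity")
  imp <- fit$variable.importance
  names(imp)[order(-imp, names(imp))]
}

#' Train a recursive-feature-elimination random forest
#'
#' Nested repeated cross-validation: in every inner analysis fold, features
#' are ranked by Gini impurity importance on the inner-training data and
#' each candidate subset size is scored by held-out AUROC; the inner fold's
#' best subset increments the selection-frequency table. The subset size
#' maximizing mean inner AUROC is chosen per outer fold, the outer held-out
#' predictions are pooled into the cross-validated AUROC, and the final
#' forest is refit on all discovery data at the modal best size (ties break
#' toward the smaller, more parsimonious size). Class imbalance is handled
#' with stratified folds and inverse-frequency class weights.
#'
#' @param x standardized numeric matrix, lesions x features (radiomic
#'   survivors plus encoded clinical covariates)
#' @param y binary labels (0/1)
#' @param config an [rfeConfig()]
#' @return an [RFEModel-class]
#' @export
rfeRfTrain <- function(x, y, config = rfeConfig()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 10)
    warning("fewer than 10 samples in a class; estimates will be unstable")
  feats <- colnames(x)
  p <- length(feats)
  sizes <- config$subsetSizes
  if (is.null(sizes)) sizes <- c(2, 4, 8, 16, 32, p)
  sizes <- sort(unique(pmin(sizes, p)))
  set.seed(config$seed)
  seedpool <- sample.int(.Machine$integer.max - 1L,
                         config$repeats * config$outerFolds *
                           (config$innerFolds * (length(sizes) + 2) + 5) +
                           10)
  si <- 0L
  nextseed <- function() {
    si <<- si + 1L
    seedpool[si]
  }
  freq <- stats::setNames(rep(0L, p), feats)
  bestSizes <- integer(0)
  cvScores <- numeric(0)
  cvLabels <- integer(0)
  for (r in seq_len(config$repeats)) {
    set.seed(nextseed())
    outer_fold <- validFolds(y, config$outerFolds)
    for (fd in seq_len(config$outerFolds)) {
      tr <- which(outer_fold != fd)
      te <- which(outer_fold == fd)
      set.seed(nextseed())
      inner_fold <- validFolds(y[tr], config$innerFolds)
      size_auc <- matrix(NA_real_, config$innerFolds, length(sizes))
      for (ifd in seq_len(config$innerFolds)) {
        it <- tr[inner_fold != ifd]
        iv <- tr[inner_fold == ifd]
        ranking <- rankByImportance(x[it, , drop = FALSE], y[it],
                                    config$nTrees, nextseed())
        for (s in seq_along(sizes)) {
          keep <- ranking[seq_len(sizes[s])]
          fit <- fitForest(x[it, keep, drop = FALSE], y[it],
                           config$nTrees, nextseed())
          size_auc[ifd, s] <- auroc(
            forestScores(fit, x[iv, keep, drop = FALSE]), y[iv])
        }
        best_s <- sizes[which.max(size_auc[ifd, ])]  # ties -> smaller
        freq[ranking[seq_len(best_s)]] <-
          freq[ranking[seq_len(best_s)]] + 1L
      }
      outer_best <- sizes[which.max(colMeans(size_auc))]
      bestSizes <- c(bestSizes, outer_best)
      ranking <- rankByImportance(x[tr, , drop = FALSE], y[tr],
                                  config$nTrees, nextseed())
      keep <- ranking[seq_len(outer_best)]
      fit <- fitForest(x[tr, keep, drop = FALSE], y[tr], config$nTrees,
                       nextseed())
      cvScores <- c(cvScores, forestScores(fit, x[te, keep, drop = FALSE]))
      cvLabels <- c(cvLabels, y[te])
    }
  }
  tabs <- table(bestSizes)
  modal <- min(as.integer(names(tabs)[tabs == max(tabs)]))
  ranking <- rankByImportance(x, y, config$nTrees, nextseed())
  selected <- ranking[seq_len(modal)]
  final <- fitForest(x[, selected, drop = FALSE], y, config$nTrees,
                     nextseed(), importance = "impurity")
  total <- config$repeats * config$outerFolds * config$innerFolds
  new("RFEModel", forest = final, selected = selected,
      bestSize = as.numeric(modal), cvAUROC = auroc(cvScores, cvLabels),
      cvScores = cvScores, cvLabels = cvLabels,
      freqTable = data.frame(feature = feats, count = as.integer(freq),
                             row.names = NULL),
      totalFolds = as.integer(total),
      config = unclass(config))
}

#' Features relevant to the classification
#'
#' A feature is relevant when it was selected in strictly more than
#' `thresholdFraction` of the analysis folds — for the printed configuration,
#' more than 10% of 250 folds, i.e. a raw fold count above 25.
#'
#' @param model an [RFEModel-class] (or its `freqTable` with `totalFolds`
#'   passed explicitly)
#' @param thresholdFraction strict selection-frequency threshold
#' @param total total analysis folds (defaults to the model's)
#' @return character vector of relevant feature ids
#' @export
relevantFeatures <- function(model, thresholdFraction = 0.10,
                             total = NULL) {
  if (is(model, "RFEModel")) {
    ft <- model@freqTable
    if (is.null(total)) total <- model@totalFolds
  } else {
    ft <- model
    if (is.null(total)) stop("total analysis folds required")
  }
  ft$feature[ft$count > thresholdFraction * total]
}

#' Score held-out lesions with a fitted RFE-RF model
#'
#' @param model an [RFEModel-class]
#' @param x standardized held-out matrix containing all selected feature
#'   columns
#' @return per-lesion positive-class vote fractions in [0, 1]
#' @export
predictScores <- function(model, x) {
  stopifnot(is(model, "RFEModel"), is.matrix(x))
  missing <- setdiff(model@selected, colnames(x))
  if (length(missing))
    stop("missing selected feature column(s): ",
         paste(head(missing, 5), collapse = ", "))
  forestScores(model@forest, x[, model@selected, drop = FALSE])
}
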
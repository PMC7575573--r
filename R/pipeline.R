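#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the classification task
#' (`"mmr"`: MMR-D vs CN-low/CN-high-like with POLE excluded; `"tmb"`:
#' TMB > 15.5 mut/Mb vs the rest), the 70/30 discovery/validation split, the
#' 3 mm rim margin, 32 gray levels, the selection-cascade settings and the
#' RFE forest layout. Every stochastic stage consumes a seed derived from
#' the single pipeline seed.
#'
#' @param task `"mmr"` or `"tmb"`
#' @param splitFraction discovery fraction, in (0, 1)
#' @param tmbCutpoint TMB-H cut-point in mut/Mb (strict `>`)
#' @param margin rim dilation margin (mm)
#' @param nBins texture gray levels
#' @param alpha stability-filter significance level
#' @param mrmrFraction mRMR retained proportion
#' @param prefilterFolds,prefilterRepeats,upsample elastic-net settings
#' @param rfe an [rfeConfig()]
#' @param seed master pipeline seed
#' @return config list of class `PipelineConfig`
#' @export
pipelineConfig <- function(task = c("mmr", "tmb"), splitFraction = 0.70,
                           tmbCutpoint = 15.5, margin = 3, nBins = 32,
                           alpha = 0.05, mrmrFraction = 0.8,
                           prefilterFolds = 5, prefilterRepeats = 10,
                           upsample = TRUE, rfe = rfeConfig(), seed = 1L) {
  task <- match.arg(task)
  if (splitFraction <= 0 || splitFraction >= 1)
    stop("splitFraction must be in (0, 1)")
  if (tmbCutpoint <= 0) stop("tmbCutpoint must be > 0")
  structure(list(task = task, splitFraction = splitFraction,
                 tmbCutpoint = tmbCutpoint, margin = margin, nBins = nBins,
                 alpha = alpha, mrmrFraction = mrmrFraction,
                 prefilterFolds = prefilterFolds,
                 prefilterRepeats = prefilterRepeats, upsample = upsample,
                 rfe = rfe, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Stratified discovery/validation split
#'
#' Splits lesions into discovery and validation sets of sizes
#' `round(fraction * n)` and the remainder, stratified on the supplied
#' labels (by default molecular subtype crossed with TMB class) so both
#' cohorts mirror the class mix. Strata of size 1 go to discovery with a
#' warning.
#'
#' @param strata per-lesion stratification labels (vector or data.frame of
#'   columns to cross)
#' @param fraction discovery fraction in (0, 1)
#' @param seed RNG seed
#' @return list with integer index vectors `discovery` and `validation`
#' @export
splitCohort <- function(strata, fraction = 0.70, seed = 1L) {
  if (is.data.frame(strata)) strata <- interaction(strata, drop = TRUE)
  n <- length(strata)
  if (n < 2) stop("need at least 2 lesions to split")
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1): both splits must be non-empty")
  n_disc <- round(fraction * n)
  set.seed(seed)
  strata <- factor(strata)
  sizes <- table(strata)
  if (any(sizes == 1))
    warning("stratum of size 1 assigned to discovery")
  ideal <- fraction * as.numeric(sizes)
  take <- floor(ideal)
  take[sizes == 1] <- 1
  short <- n_disc - sum(take)
  if (short > 0) {
    ord <- order(-(ideal - floor(ideal)))
    ord <- ord[take[ord] < sizes[ord]]
    take[ord[seq_len(min(short, length(ord)))]] <-
      take[ord[seq_len(min(short, length(ord)))]] + 1
  } else if (short < 0) {
    ord <- order(ideal - floor(ideal))
    ord <- ord[take[ord] > 0 & sizes[ord] > 1]
    take[ord[seq_len(min(-short, length(ord)))]] <-
      take[ord[seq_len(min(-short, length(ord)))]] - 1
  }
  disc <- integer(0)
  for (s in seq_along(sizes)) {
    idx <- which(strata == levels(strata)[s])
    disc <- c(disc, if (length(idx) == 1) idx else
      sample(idx, take[s]))
  }
  disc <- sort(disc)
  list(discovery = disc, validation = setdiff(seq_len(n), disc))
}

#' Derive binary task labels and the inclusion mask
#'
#' `mmr` task: positives are MMR-D lesions, negatives CN-low-like and
#' CN-high-like; POLE lesions are excluded. `tmb` task: positives are
#' lesions with TMB strictly above the cut-point; all subtypes included.
#'
#' @param clinical data.frame with `subtype` and `tmb` columns
#' @param task `"mmr"` or `"tmb"`
#' @param tmbCutpoint cut-point in mut/Mb
#' @return list with logical `include` and integer `labels` (0/1, `NA` for
#'   excluded lesions)
#' @export
deriveLabels <- function(clinical, task = c("mmr", "tmb"),
                         tmbCutpoint = 15.5) {
  task <- match.arg(task)
  known <- c("POLE", "MMR-D", "CN-low-like", "CN-high-like")
  bad <- setdiff(unique(clinical$subtype), known)
  if (length(bad))
    stop("unknown subtype code(s): ", paste(bad, collapse = ", "))
  if (task == "mmr") {
    include <- clinical$subtype != "POLE"
    if (!any(include)) stop("no lesions left after POLE exclusion")
    labels <- ifelse(clinical$subtype == "MMR-D", 1L, 0L)
    labels[!include] <- NA_integer_
  } else {
    include <- rep(TRUE, nrow(clinical))
    labels <- as.integer(clinical$tmb > tmbCutpoint)
  }
  list(include = include, labels = labels)
}

#' Encode clinical covariates for the classifier
#'
#' Age numeric; histology one-hot against an endometrioid reference; grade
#' and stage as binaries. These bypass the radiomic selection cascade and
#' are appended to the surviving radiomic features.
#'
#' @param clinical data.frame with `age`, `histology`, `grade`, `stage`
#' @return numeric matrix, lesions x encoded covariates
#' @export
encodeClinical <- function(clinical) {
  hl <- c("serous", "clear_cell", "carcinosarcoma", "other_high_grade")
  m <- cbind(
    clin_age = as.numeric(clinical$age),
    vapply(hl, function(h) as.numeric(clinical$histology == h),
           numeric(nrow(clinical))),
    clin_grade_poor = as.numeric(clinical$grade == "poor"),
    clin_stage_extra = as.numeric(clinical$stage == "extra_uterine"))
  colnames(m) <- c("clin_age", paste0("clin_hist_", hl),
                   "clin_grade_poor", "clin_stage_extra")
  m
}

#' Run the full clinical-radiomic pipeline on a cohort
#'
#' Orchestrates feature extraction (1 mm resampling, 3 mm rim, 200-feature
#' panel), the stratified 70/30 split, task label derivation, the
#' discovery-only selection cascade and z-score standardization, RFE-RF
#' training, held-out prediction and the full evaluation report. The whole
#' run is reproducible from `(cohort, config)`.
#'
#' @param cohort a [PhantomCohort-class], or `NULL` when `features` is given
#' @param config a [pipelineConfig()]
#' @param features optional precomputed `SummarizedExperiment` from
#'   [extractCohortFeatures()] (skips extraction; useful when running both
#'   tasks on one cohort)
#' @return list with `evaluation`, `selection`, `model`, `split`, `labels`,
#'   `features`, `standardization`
#' @export
runPipeline <- function(cohort, config = pipelineConfig(),
                        features = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(features))
    features <- extractCohortFeatures(cohort, margin = config$margin,
                                      nBins = config$nBins)
  clin <- as.data.frame(SummarizedExperiment::colData(features))
  xr <- featureMatrix(features)

  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4)

  tmbClass <- clin$tmb > config$tmbCutpoint
  split <- splitCohort(data.frame(subtype = clin$subtype, tmb = tmbClass),
                       fraction = config$splitFraction, seed = seeds[1])

  lab <- deriveLabels(clin, config$task, config$tmbCutpoint)
  disc <- intersect(split$discovery, which(lab$include))
  vali <- intersect(split$validation, which(lab$include))
  y_disc <- lab$labels[disc]
  y_vali <- lab$labels[vali]

  selection <- runSelectionCascade(
    xr[disc, , drop = FALSE], y_disc, clin$scanner[disc],
    alpha = config$alpha, mrmrFraction = config$mrmrFraction,
    folds = config$prefilterFolds, repeats = config$prefilterRepeats,
    upsample = config$upsample, seed = seeds[2])
  surv <- survivingFeatures(selection)

  xc <- encodeClinical(clin)
  x_disc <- cbind(xr[disc, surv, drop = FALSE], xc[disc, , drop = FALSE])
  x_vali <- cbind(xr[vali, surv, drop = FALSE], xc[vali, , drop = FALSE])
  zs <- zscoreStandardize(x_disc, x_vali)

  rfe <- config$rfe
  rfe$seed <- seeds[3]
  model <- rfeRfTrain(zs$train, y_disc, rfe)

  evaluation <- evaluateModel(model, zs$applied, y_vali)
  list(evaluation = evaluation, selection = selection, model = model,
       split = split, labels = lab, features = features,
       standardization = zs[c("center", "scale")])
}

#' Write pipeline artifacts to a directory
#'
#' Evaluation report and selection report as JSON, the selection-frequency
#' table and feature associations as CSV.
#'
#' @param result the list returned by [runPipeline()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
writePipelineReport <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- result$evaluation
  jsonlite::write_json(list(
    cv_auroc = ev$cv_auroc, cv_auroc_ci = ev$cv_auroc_ci,
    test_auroc = ev$test_auroc, test_auroc_ci = ev$test_auroc_ci,
    delong_p = ev$delong_p, confusion = ev$confusion,
    relevant_features = ev$relevant_features,
    n_train = ev$n_train, n_test = ev$n_test),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  st <- selectionStages(result$selection)
  jsonlite::write_json(lapply(st, function(s)
    list(n_in = length(s$features_in), n_out = length(s$features_out),
         features_out = s$features_out)),
    file.path(dir, "selection.json"), auto_unbox = TRUE)
  write.csv(selectionFrequencies(result$model),
            file.path(dir, "selection_frequencies.csv"), row.names = FALSE)
  if (!is.null(ev$associations))
    write.csv(ev$associations, file.path(dir, "associations.csv"),
              row.names = FALSE)
  invisible(dir)
}
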
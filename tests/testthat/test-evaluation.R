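test_that("AUROC matches pair-counting enumeration and handles ties", {
  sc <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0, 0, 1, 1)
  # enumerate all 4 positive-negative pairs by hand
  pos <- sc[y == 1]; neg <- sc[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auroc(sc, y), mean(pairs))
  expect_equal(auroc(sc, y), 0.75)

  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "one class absent")
})

test_that("AUROC properties: label flip and U-statistic equivalence", {
  set.seed(61)
  for (k in 1:5) {
    sc <- round(rnorm(30), 1)  # coarse scores force ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(sc, y), 1 - auroc(sc, 1 - y))
    u <- unname(suppressWarnings(
      wilcox.test(sc[y == 1], sc[y == 0])$statistic))
    expect_equal(auroc(sc, y), u / (sum(y == 1) * sum(y == 0)))
  }
})

test_that("DeLong variance matches the brute-force placement oracle and the
           self-comparison gives p = 1", {
  sc <- c(0.2, 0.9, 0.75, 0.65, 0.5, 0.8, 0.15, 0.7)
  y <- c(0, 1, 0, 1, 0, 1, 0, 1)
  pos <- sc[y == 1]; neg <- sc[y == 0]
  v10 <- sapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)))
  v01 <- sapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)))
  vref <- var(v10) / length(pos) + var(v01) / length(neg)
  expect_equal(RimRadiomics:::delongVariance(sc, y), vref)

  dl <- delongTest(sc, y, sc, y)
  expect_equal(dl$p, 1.0)
  expect_equal(dl$auc_a, dl$auc_b)
  expect_true(dl$ci_a[1] <= dl$auc_a && dl$auc_a <= dl$ci_a[2])
})

test_that("DeLong results agree with an independent reference
           implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  y <- rbinom(60, 1, 0.5)
  sc <- rnorm(60) + y
  dl <- delongTest(sc, y, sc, y)
  ref <- pROC::ci.auc(pROC::roc(y, sc, quiet = TRUE), method = "delong")
  expect_equal(dl$auc_a, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(dl$ci_a, as.numeric(ref[c(1, 3)]), tolerance = 1e-9)

  y2 <- rbinom(50, 1, 0.5)
  sc2 <- rnorm(50) + 0.3 * y2
  dl2 <- delongTest(sc, y, sc2, y2)
  ref2 <- pROC::roc.test(pROC::roc(y, sc, quiet = TRUE),
                         pROC::roc(y2, sc2, quiet = TRUE),
                         method = "delong", paired = FALSE)
  expect_equal(dl2$p, ref2$p.value, tolerance = 1e-3)
})

test_that("DeLong CI width shrinks with sample size at fixed AUROC", {
  width <- sapply(c(20, 80, 320), function(n) {
    set.seed(n)
    y <- rep(c(0, 1), n / 2)
    sc <- rnorm(n) + 0.8 * y
    dl <- delongTest(sc, y, sc, y)
    diff(dl$ci_a)
  })
  expect_true(all(diff(width) < 0))
})

test_that("confusion metrics match direct ratios with exact CIs", {
  # TP=7, FN=4, FP=8, TN=23
  truth <- c(rep(1, 11), rep(0, 31))
  pred <- c(rep(1, 7), rep(0, 4), rep(1, 8), rep(0, 23))
  cm <- confusionMetrics(pred, truth)
  est <- setNames(cm$estimate, cm$metric)
  expect_equal(unname(est["sensitivity"]), 7 / 11)
  expect_equal(unname(est["specificity"]), 23 / 31)
  expect_equal(unname(est["ppv"]), 7 / 15)
  expect_equal(unname(est["npv"]), 23 / 27)
  # Clopper-Pearson CIs contain the point estimate
  expect_true(all(cm$lower <= cm$estimate & cm$estimate <= cm$upper))
  expect_equal(cm$lower[1], binom.test(7, 11)$conf.int[1])

  all_right <- confusionMetrics(truth, truth)
  expect_true(all(all_right$estimate == 1))
  expect_true(all(all_right$upper == 1))

  flipped <- suppressWarnings(confusionMetrics(1 - truth, truth))
  est_f <- setNames(flipped$estimate, flipped$metric)
  expect_equal(unname(est_f["sensitivity"]), 0)
  expect_equal(unname(est_f["specificity"]), 0)

  expect_warning(cm2 <- confusionMetrics(rep(0, 10), rep(c(0, 1), 5)),
                 "ppv undefined")
  expect_true(is.na(cm2$estimate[cm2$metric == "ppv"]))
})

test_that("Mann-Whitney associations use exact small-sample p and BH
           step-up", {
  x <- cbind(f1 = c(1, 2, 3, 4, 5, 6))
  y <- c(1, 1, 1, 0, 0, 0)
  mw <- mannWhitneyBH(x, y)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2/20 rank assignments as extreme
  expect_equal(mw$p_adj, mw$p)  # single feature: adjusted = raw

  # BH on the printed toy p-values (0.01, 0.02, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))

  # constant feature convention
  xc <- cbind(f1 = rep(2, 6), f2 = c(1, 2, 3, 4, 5, 6))
  mwc <- mannWhitneyBH(xc, y)
  expect_equal(mwc$p[1], 1.0)

  # BH properties on random panels
  set.seed(81)
  xr <- matrix(rnorm(20 * 8), 20, 8,
               dimnames = list(NULL, paste0("g", 1:8)))
  yr <- rep(c(0, 1), 10)
  mr <- mannWhitneyBH(xr, yr)
  expect_true(all(mr$p_adj >= mr$p))
  expect_true(all(mr$p_adj <= 1))
  ord <- order(mr$p)
  expect_true(all(diff(mr$p_adj[ord]) >= -1e-12))
})
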
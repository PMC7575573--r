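make_features <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  x
}

test_that("stability filter removes scanner-confounded features and keeps
           the rest", {
  n <- 105
  scanner <- rep(c("A", "B", "C"), each = 35)
  x <- make_features(n, 10, seed = 2)
  x[, "f001"] <- as.numeric(factor(scanner)) + rnorm(n, 0, 0.01)
  st <- stabilityFilter(x, scanner, alpha = 0.05)
  expect_false("f001" %in% st$features_out)
  expect_lt(st$scores["f001"], 1e-10)

  # single scanner group: filter skipped, everything retained
  expect_warning(st1 <- stabilityFilter(x, rep("A", n)), "skipped")
  expect_identical(st1$features_out, colnames(x))

  # constant feature: retained with NA score
  x[, "f002"] <- 1
  st2 <- stabilityFilter(x, scanner)
  expect_true("f002" %in% st2$features_out)
  expect_true(is.na(st2$scores["f002"]))
})

test_that("stability filter type-I removal rate under permuted labels is
           approximately alpha", {
  set.seed(9)
  n <- 90; p <- 400
  x <- make_features(n, p, seed = 9)
  scanner <- sample(rep(c("A", "B", "C"), each = 30))
  st <- stabilityFilter(x, scanner, alpha = 0.05)
  removed <- 1 - length(st$features_out) / p
  # alpha +/- 2 binomial sd
  expect_lt(abs(removed - 0.05), 2 * sqrt(0.05 * 0.95 / p) + 1e-9)
})

test_that("mRMR retains ceiling(fraction * n) with relevance first and
           redundancy penalized", {
  set.seed(4)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  x <- make_features(n, 10, seed = 4)
  st <- mrmrSelect(x, y, 0.8)
  expect_length(st$features_out, 8)  # ceil(0.8 * 10)
  expect_length(mrmrSelect(x, y, 0.75)$features_out, 8)  # ceil(7.5)

  # a feature equal to the label ranks first
  x[, "f005"] <- y
  expect_identical(mrmrSelect(x, y, 0.5)$features_out[1], "f005")

  # an exact duplicate of the top feature ranks below a weaker but
  # independent informative feature
  x2 <- make_features(n, 4, seed = 14)
  x2[, "f001"] <- y + rnorm(n, 0, 0.3)
  x2[, "f002"] <- x2[, "f001"]              # duplicate of the top feature
  x2[, "f003"] <- y + rnorm(n, 0, 1.2)      # weaker independent signal
  out <- mrmrSelect(x2, y, 1.0)$features_out
  expect_identical(out[1], "f001")
  expect_lt(which(out == "f003"), which(out == "f002"))

  expect_error(mrmrSelect(x, y, 0), "fraction")
  expect_error(mrmrSelect(x, y, 1.2), "fraction")
  expect_error(mrmrSelect(x, rep(1, n), 0.8), "classes")
})

test_that("elastic-net prefilter recovers planted effects and prunes noise
           under the null", {
  planted <- sprintf("f%03d", 1:5)
  hits <- 0
  found <- 0
  runs <- 6
  for (r in seq_len(runs)) {
    set.seed(100 + r)
    n <- 105
    x <- make_features(n, 50, seed = 200 + r)
    eta <- rowSums(x[, planted])  # log-odds effect 1.0 each
    y <- rbinom(n, 1, plogis(eta))
    st <- prefilterElasticNet(x, y, folds = 5, repeats = 10, seed = r)
    hits <- hits + all(planted %in% st$features_out)
    found <- found + sum(planted %in% st$features_out)
  }
  expect_gte(hits, runs - 1)
  expect_gte(found / (5 * runs), 0.9)

  # null labels: the one-SE penalty typically drops the majority of noise
  # (chance correlations keep occasional draws denser, so test the median)
  kept <- vapply(1:3, function(r) {
    set.seed(300 + r)
    xn <- matrix(rnorm(80 * 40), 80, 40,
                 dimnames = list(NULL, sprintf("f%03d", 1:40)))
    yn <- rbinom(80, 1, 0.5)
    length(prefilterElasticNet(xn, yn, repeats = 10,
                               seed = r)$features_out)
  }, numeric(1))
  expect_lt(median(kept), 20)
})

test_that("upsampling balances training folds", {
  set.seed(6)
  y <- c(rep(1, 10), rep(0, 40))
  idx <- RimRadiomics:::upsampleIdx(y)
  expect_identical(unname(table(y[idx])["0"]), unname(table(y[idx])["1"]))
})

test_that("z-score standardization uses sample sd and training parameters
           only", {
  tr <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  zs <- zscoreStandardize(tr)
  expect_equal(as.numeric(zs$train), c(-1, 0, 1))  # sample-sd convention

  # idempotence: applying stored parameters to the training table
  zs2 <- zscoreStandardize(tr, tr)
  expect_equal(zs2$applied, zs2$train)

  # held-out data transformed with training parameters, not its own
  te <- matrix(c(4, 5, 6), 3, 1, dimnames = list(NULL, "a"))
  zs3 <- zscoreStandardize(tr, te)
  expect_equal(as.numeric(zs3$applied), c(2, 3, 4))

  cst <- matrix(7, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(zc <- zscoreStandardize(cst), "constant")
  expect_true(all(zc$train == 0))

  expect_error(zscoreStandardize(tr, matrix(0, 3, 1,
    dimnames = list(NULL, "b"))), "match")
})

test_that("the cascade is monotone, ordered, and blind to held-out data", {
  set.seed(12)
  n <- 80
  x <- make_features(n, 30, seed = 12)
  y <- rbinom(n, 1, plogis(rowSums(x[, 1:3])))
  scanner <- sample(c("A", "B"), n, replace = TRUE)
  rep1 <- runSelectionCascade(x, y, scanner, repeats = 3, seed = 2)
  st <- selectionStages(rep1)
  expect_identical(names(st), c("stability", "mrmr", "prefilter"))
  sizes <- c(30, vapply(st, function(s) length(s$features_out), numeric(1)))
  expect_true(all(diff(sizes) <= 0))
  expect_identical(length(st$mrmr$features_out),
                   as.integer(ceiling(0.8 * length(st$stability$features_out))))
  expect_true(all(survivingFeatures(rep1) %in% colnames(x)))
})
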
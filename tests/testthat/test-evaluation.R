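test_that("per-class metrics match direct arithmetic", {
  # perfect diagonal: every metric 1
  perf <- perClassMetrics(diag(c(5, 3, 7)))
  expect_true(all(as.matrix(perClass(perf)[, -1]) == 1))
  expect_equal(accuracy(perf), 1)

  # 2-class worked example, truth in rows: [[8,2],[1,9]]
  conf <- matrix(c(8, 1, 2, 9), 2, 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
  rep <- perClassMetrics(conf)
  pc <- perClass(rep)
  expect_equal(pc$sensitivity[1], 8 / 10)
  expect_equal(pc$specificity[1], 9 / 10)
  expect_equal(pc$precision[1], 8 / 9)
  expect_equal(pc$fScore[1], 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  expect_equal(accuracy(rep), 17 / 20)
  # row sums = class counts
  expect_equal(rowSums(confusionMatrix(rep)), c(x = 10, y = 10))
  expect_error(perClassMetrics(matrix(1, 2, 3)), "square")
  # zero-denominator ratios surface as NaN with a warning
  expect_warning(z <- perClassMetrics(matrix(c(4, 0, 0, 0), 2, 2)), "NaN")
  expect_true(is.nan(perClass(z)$precision[2]))
})

test_that("macro averaging is the unweighted class mean", {
  expect_equal(macroAverage(c(0.7, 0.7, 0.7)), 0.7)
  expect_equal(macroAverage(c(0, 1)), 0.5)
  rep <- perClassMetrics(diag(c(2, 2)))
  expect_equal(unname(macroAverage(perClass(rep))[["fScore"]]), 1)
})

test_that("F-score identity holds for published per-class rates", {
  # printed sensitivity/precision pairs reproduce the printed F-scores
  # within half an ulp of their 4-decimal rounding
  sens <- c(0.8020, 0.8264, 0.8285, 0.7946, 0.9239, 0.9777, 0.7977, 0.8802)
  prec <- c(0.9916, 0.9777, 0.9417, 1.0000, 0.9444, 0.8421, 0.9723, 0.9907)
  fPrinted <- c(0.8868, 0.8957, 0.8815, 0.8856, 0.9341, 0.9049, 0.8764,
                0.9322)
  expect_lt(max(abs(fScore(sens, prec) - fPrinted)), 1e-4)
  expect_equal(fScore(0.8020, 0.9916), 0.8868, tolerance = 1e-4)
  # macro mean of the eight printed F-scores, on the percent scale
  expect_equal(100 * macroAverage(fPrinted), 89.97, tolerance = 0.005)
})

test_that("every classifier family runs through stratified CV", {
  tab <- small_table(seed = 5, n = 60, p = 5, ninf = 2, k = 3, effect = 6)
  for (kind in c("DT", "LD", "NB", "SVM", "KNN")) {
    rep <- stratifiedCV(tab$X, tab$y, classifierSpec(kind), k = 4, seed = 1)
    expect_s4_class(rep, "MetricsReport")
    expect_equal(sum(confusionMatrix(rep)), 60)       # conservation
    expect_gt(accuracy(rep), 0.8)                     # well-separated table
    expect_true(all(aucOvr(rep) >= 0 & aucOvr(rep) <= 1))
  }
  expect_error(classifierSpec("RF"))
})

test_that("a perfectly separable table gives accuracy 1 with SVM", {
  tab <- generateFeatureTable(synthTableSpec(nSamples = 200, nFeatures = 5,
                                             nInformative = 2, nClasses = 2,
                                             effectSize = 10, seed = 1))
  rep <- stratifiedCV(tab$X, tab$y, classifierSpec("SVM"), k = 10, seed = 1)
  expect_equal(accuracy(rep), 1)
  expect_equal(aucOvr(rep)[["macro"]], 1)
})

test_that("label permutation drops accuracy to chance", {
  tab <- generateFeatureTable(synthTableSpec(nSamples = 100, nFeatures = 6,
                                             nInformative = 2, nClasses = 2,
                                             effectSize = 4, seed = 3))
  set.seed(11)
  yp <- sample(tab$y)
  rep <- stratifiedCV(tab$X, yp, classifierSpec("SVM"), k = 10, seed = 2)
  expect_gt(accuracy(rep), 0.3)                       # ~4 sd binomial band
  expect_lt(accuracy(rep), 0.7)
})

test_that("fold assignment is stratified, seeded and reproducible", {
  tab <- small_table(seed = 8, n = 55, k = 3)
  r1 <- stratifiedCV(tab$X, tab$y, classifierSpec("LD"), k = 5, seed = 4)
  r2 <- stratifiedCV(tab$X, tab$y, classifierSpec("LD"), k = 5, seed = 4)
  expect_identical(r1@foldAssignments, r2@foldAssignments)
  expect_identical(confusionMatrix(r1), confusionMatrix(r2))
  r3 <- stratifiedCV(tab$X, tab$y, classifierSpec("LD"), k = 5, seed = 5)
  expect_false(identical(r1@foldAssignments, r3@foldAssignments))
  # every sample predicted exactly once; per-class fold sizes within 1
  expect_equal(sum(confusionMatrix(r1)), 55)
  for (cl in levels(tab$y)) {
    szs <- table(r1@foldAssignments[tab$y == cl])
    expect_lte(max(szs) - min(szs), 1)
  }
  # small classes reduce k with a warning (the lopsided labels may also
  # produce empty prediction columns, hence NaN-ratio warnings)
  y2 <- factor(c(rep("a", 50), rep("b", 5)))
  w <- capture_warnings(stratifiedCV(tab$X, y2, classifierSpec("LD"),
                                     k = 10, seed = 1))
  expect_true(any(grepl("reduced", w)))
})

test_that("a random scorer has AUC near one half", {
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    y <- factor(rep(c("a", "b"), 50))
    sc <- cbind(a = runif(100), b = runif(100))
    fundusNCAR:::ovr_aucs(y, sc)[["macro"]]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("paper-mode pipeline on a feature table reports full metrics", {
  tab <- small_table(seed = 10, n = 60, p = 10, ninf = 3, k = 3, effect = 4)
  res <- runPipeline(labels = tab$y, features = tab$X,
                     ncaCfg = ncaConfig(maxIters = 20), n1 = 6, n2 = 4,
                     cvFolds = 4, seed = 1)
  expect_s4_class(res$metrics, "MetricsReport")
  expect_equal(nSelected(res$selection), 4L)
  expect_equal(nrow(perClass(res$metrics)), 3L)
  expect_gt(accuracy(res$metrics), 0.8)
})

test_that("honest-mode accuracy does not beat paper mode in expectation", {
  # weak signal + many noise columns: selecting on all data leaks the
  # held-out labels into the feature choice, inflating paper-mode CV
  accP <- accH <- numeric(6)
  for (s in 1:6) {
    tab <- generateFeatureTable(synthTableSpec(
      nSamples = 90, nFeatures = 40, nInformative = 3, nClasses = 3,
      effectSize = 1.2, seed = 100 + s))
    p <- runPipeline(labels = tab$y, features = tab$X,
                     ncaCfg = ncaConfig(maxIters = 25), n1 = 15, n2 = 8,
                     cvFolds = 3, mode = "paper", seed = s)
    h <- runPipeline(labels = tab$y, features = tab$X,
                     ncaCfg = ncaConfig(maxIters = 25), n1 = 15, n2 = 8,
                     cvFolds = 3, mode = "honest", seed = s)
    accP[s] <- accuracy(p$metrics)
    accH[s] <- accuracy(h$metrics)
  }
  expect_lte(mean(accH), mean(accP) + 0.02)
})
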
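test_that("neighbour probabilities cover the degenerate two-sample cases", {
  X <- matrix(c(0, 1), ncol = 1)
  expect_equal(ncaProbabilities(X, c("a", "b"), w = 1), c(0, 0))
  expect_equal(ncaProbabilities(X, c("a", "a"), w = 1), c(1, 1))
  expect_error(ncaProbabilities(X[1, , drop = FALSE], "a", w = 1),
               "two samples")
})

test_that("neighbour probabilities match brute-force enumeration", {
  X <- matrix(c(0, 0.1, 1.0), ncol = 1)
  y <- c("A", "A", "B")
  expect_equal(ncaProbabilities(X, y, w = 1, sigma = 1),
               oracle_nca_P(X, y, w = 1, sigma = 1), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(4:9, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("u", "v"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("u", "v"), y[1])
    w <- runif(p, 0, 2)
    sg <- runif(1, 0.4, 2)
    expect_equal(ncaProbabilities(X, y, w, sg), oracle_nca_P(X, y, w, sg),
                 tolerance = 1e-10)
  }
})

test_that("objective reduces to its closed forms in degenerate settings", {
  cfg <- ncaConfig(lambdaReg = 0.25)
  # one sample per class: every P_i = 0, so F = -lambda * sum(w^2)
  X <- matrix(c(0, 3, 7), ncol = 1)
  w <- c(1.3)
  expect_equal(ncaObjective(X, c("a", "b", "c"), w, cfg), -0.25 * sum(w^2))
  # w = 0: all distances vanish, p_ij uniform over the n-1 neighbours
  y <- c("a", "a", "b")
  expect_equal(ncaObjective(X, y, 0, cfg), mean(c(0.5, 0.5, 0)))
  # toy instance agrees with the enumeration oracle
  Xt <- matrix(c(0, 0.1, 1.0), ncol = 1)
  expect_equal(ncaObjective(Xt, y, 1, cfg),
               oracle_nca_objective(Xt, y, 1, sigma = 1, lambda = 0.25),
               tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  worst <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- sample(5:10, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("a", "b"), y[1])
    w <- runif(p, 0.1, 1.5)
    cfg <- ncaConfig(lambdaReg = runif(1, 0, 0.5),
                     kernelWidth = runif(1, 0.5, 1.5))
    g <- ncaGradient(X, y, w, cfg)
    eps <- 1e-6
    for (r in seq_len(p)) {
      wp <- w; wp[r] <- w[r] + eps
      wm <- w; wm[r] <- w[r] - eps
      num <- (ncaObjective(X, y, wp, cfg) - ncaObjective(X, y, wm, cfg)) /
        (2 * eps)
      worst <- max(worst, abs(num - g[r]) / max(abs(num), abs(g[r]), 1e-8))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("gradient symmetries hold", {
  set.seed(2)
  X <- matrix(rnorm(16), 8, 2)
  X <- cbind(X, X[, 2])                               # duplicate column
  y <- rep(c("a", "b"), 4)
  cfg <- ncaConfig(lambdaReg = 0.1)
  g <- ncaGradient(X, y, c(0.7, 1.2, 1.2), cfg)
  expect_equal(g[2], g[3], tolerance = 1e-12)         # identical columns
  expect_equal(ncaGradient(X, y, c(0, 0, 0), cfg), rep(0, 3))  # w = 0
})

test_that("gradient ascent maximises the objective with a monotone trace", {
  tab <- small_table(seed = 3)
  fit <- fitNCA(tab$X, tab$y, ncaConfig(maxIters = 40))
  tr <- objectiveTrace(fit)
  expect_gt(length(tr), 2L)
  expect_true(all(diff(tr) >= -1e-12))
  expect_error(fitNCA(tab$X, factor(rep("a", nrow(tab$X)))),
               "unidentified")
})

test_that("strong regularisation shrinks every weight towards zero", {
  tab <- small_table(seed = 6, n = 40)
  fit <- fitNCA(tab$X, tab$y, ncaConfig(lambdaReg = 10, maxIters = 60))
  expect_lt(max(abs(featureWeights(fit))), 0.05)
})

test_that("fitted weights rank a separating feature above pure noise", {
  # feature 1 separates tight clusters; feature 2 is noise
  set.seed(44)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(y == "a", -1, 1) + rnorm(n, sd = 0.15), rnorm(n))
  fit <- fitNCA(X, y, ncaConfig(maxIters = 50))
  w <- featureWeights(fit)
  expect_gt(w[1], w[2])
  # grid-search oracle over (w1, w2) confirms the maximiser orders the
  # same way
  Xs <- scale(X)
  cfg <- ncaConfig()
  grid <- expand.grid(w1 = seq(0, 2.5, by = 0.25), w2 = seq(0, 2.5, by = 0.25))
  vals <- apply(grid, 1, function(g)
    oracle_nca_objective(Xs, y, c(g[1], g[2]), sigma = 1, lambda = 1 / n))
  best <- grid[which.max(vals), ]
  expect_gt(best$w1, best$w2)
})

test_that("a one-feature fit agrees with a dense grid search", {
  set.seed(91)
  n <- 30
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(ifelse(y == "a", -0.6, 0.6) + rnorm(n, sd = 0.4), ncol = 1)
  cfg <- ncaConfig(lambdaReg = 0.25, maxIters = 200, tol = 1e-9,
                   standardize = FALSE)
  fit <- fitNCA(X, y, cfg)
  ws <- seq(0, 3, by = 0.002)
  vals <- vapply(ws, function(w)
    oracle_nca_objective(X, y, w, sigma = 1, lambda = 0.25), numeric(1))
  expect_lt(abs(abs(featureWeights(fit)) - ws[which.max(vals)]), 1e-2)
})

test_that("column permutation permutes the fitted weights identically", {
  tab <- small_table(seed = 12, n = 50, p = 5)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  f1 <- fitNCA(tab$X, tab$y, ncaConfig(maxIters = 30))
  f2 <- fitNCA(tab$X[, perm], tab$y, ncaConfig(maxIters = 30))
  expect_equal(unname(featureWeights(f2)), unname(featureWeights(f1)[perm]),
               tolerance = 1e-10)
})

test_that("probability rows are normalised for random inputs", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(4:12, 1); p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("a", "b", "c"), n, replace = TRUE)
    w <- runif(p, 0, 2)
    pm <- fundusNCAR:::nca_prob_matrix(
      fundusNCAR:::abs_diff_matrix(X), factor(y), w, 1)
    expect_equal(rowSums(pm$p), rep(1, n), tolerance = 1e-10)
    expect_true(all(pm$P >= 0 & pm$P <= 1 + 1e-12))
    expect_true(all(diag(pm$p) == 0))
  }
})

test_that("weight thresholding keeps exactly the >= boundary", {
  expect_equal(selectByWeight(c(0.0004, 0.0005, 0.1), 0.0005),
               c(FALSE, TRUE, TRUE))
  expect_true(all(selectByWeight(rnorm(10), -Inf)))
  expect_warning(m <- selectByWeight(c(0.1, 0.2), 10), "empty")
  expect_false(any(m))
})
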
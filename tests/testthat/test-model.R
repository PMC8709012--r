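test_that("default architecture yields 350 deep features for a 125px image", {
  m <- buildModel(modelConfig(nClasses = 8), seed = 1)
  img <- array(runif(125 * 125 * 3), c(125, 125, 3, 1))
  fs <- extractDeepFeatures(m, img)
  expect_equal(dim(featureMatrix(fs)), c(1L, 350L))
})

test_that("variants differ exactly by skip connections and the LSTM stage", {
  base <- tiny_config("rcnn_lstm")
  mR <- buildModel(base, seed = 1)
  cfgC <- tiny_config("cnn_lstm")
  mC <- buildModel(cfgC, seed = 1)
  # block 1 changes channels, block 2 strides: both carry projections in
  # the residual variants and none otherwise
  expect_false(is.null(mR@params$blocks[[1]]$proj))
  expect_false(is.null(mR@params$blocks[[2]]$proj))
  expect_true(is.null(mC@params$blocks[[1]]$proj))
  expect_true(is.null(mC@params$blocks[[2]]$proj))
  # lstm stage present iff *_lstm variant
  mF <- buildModel(tiny_config("rcnn"), seed = 1)
  expect_true(is.null(mF@params$lstm))
  expect_false(is.null(mR@params$lstm))
})

test_that("parameter count equals the closed-form sum over layer shapes", {
  cfg <- modelConfig(nResidualBlocks = 1L, stemFilters = 4L,
                     blockFilters = 4L, lstmUnits = 8L, fc1Width = 16L,
                     nClasses = 2L, inputSize = 32L, variant = "rcnn_lstm")
  m <- buildModel(cfg, seed = 3)
  # arithmetic oracle: conv = k*k*inC*outC + outC, BN = 2*outC,
  # LSTM = 4*(U*(U+D) + U), FC = out*in + out.  One block, stride 1,
  # equal channels: identity skip, no projection.  Final map 32x32x4,
  # so the LSTM input is one row = 32*4 = 128 wide.
  stem <- 3 * 3 * 3 * 4 + 4 + 2 * 4
  block <- 2 * (3 * 3 * 4 * 4 + 4 + 2 * 4)
  lstm <- 4 * (8 * (8 + 128) + 8)
  fc <- (16 * 8 + 16) + (2 * 16 + 2)
  expect_equal(countParams(m), stem + block + lstm + fc)
})

test_that("too-small inputs are rejected with the minimum size", {
  cfg <- modelConfig(nResidualBlocks = 6L,
                     blockFilters = rep(4L, 6), inputSize = 4L,
                     nClasses = 2L)
  expect_error(buildModel(cfg), "minimum is")
})

test_that("fold/unfold is the documented bijection", {
  m <- array(seq_len(2 * 2 * 1), c(2, 2, 1))          # [[a,c],[b,d]] columns
  s <- foldToSequence(m)
  expect_equal(dim(s), c(2L, 2L))
  expect_equal(s[1L, ], c(m[1, 1, 1], m[1, 2, 1]))    # row 1, w-major
  expect_equal(s[2L, ], c(m[2, 1, 1], m[2, 2, 1]))
  one <- array(rnorm(5), c(1, 1, 5))                  # 1x1xC: one timestep
  expect_equal(dim(foldToSequence(one)), c(1L, 5L))
  expect_equal(as.numeric(foldToSequence(one)), as.numeric(one))
  set.seed(4)
  arr <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  expect_equal(unfoldSequence(foldToSequence(arr), W = 4, C = 5), arr)
  # w-major then channel ordering within a timestep
  expect_equal(foldToSequence(arr)[2L, ], as.numeric(arr[2, , ]))
})

test_that("zeroed residual blocks act as the identity on their input", {
  # conv -> BN -> ReLU -> conv -> BN with all-zero weights produces 0,
  # so skip-add + ReLU returns the (non-negative) block input unchanged
  set.seed(6)
  x <- array(abs(rnorm(6 * 6 * 2 * 3)), c(6, 6, 3, 2))    # (H, W, N, C)
  zeroconv <- list(W = matrix(0, 3 * 3 * 2, 2), b = c(0, 0))
  bn <- list(gamma = c(1, 1), beta = c(0, 0))
  run <- list(mean = c(0, 0), var = c(1, 1))
  c1 <- fundusNCAR:::conv_forward(x, zeroconv$W, zeroconv$b, 3, 3, 1, 1)
  b1 <- fundusNCAR:::bn_forward(c1$out, bn$gamma, bn$beta, run, "train")
  r1 <- fundusNCAR:::relu_forward(b1$out)
  c2 <- fundusNCAR:::conv_forward(r1$out, zeroconv$W, zeroconv$b, 3, 3, 1, 1)
  b2 <- fundusNCAR:::bn_forward(c2$out, bn$gamma, bn$beta, run, "train")
  out <- fundusNCAR:::relu_forward(b2$out + x)$out    # skip add, post ReLU
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("softmax head emits probabilities and training is deterministic", {
  cfg <- tiny_config(nClasses = 3L)
  m <- buildModel(cfg, seed = 2)
  set.seed(10)
  imgs <- array(runif(12 * 12 * 3 * 6), c(12, 12, 3, 6))
  pr <- predictModel(m, imgs)
  expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-6)
  # same seed twice: identical features; different seed: different weights
  f1 <- featureMatrix(extractDeepFeatures(m, imgs))
  f2 <- featureMatrix(extractDeepFeatures(m, imgs))
  expect_identical(f1, f2)
  m2 <- buildModel(cfg, seed = 3)
  expect_false(identical(featureMatrix(extractDeepFeatures(m2, imgs)), f1))
  # empty input: 0-row matrix
  e <- extractDeepFeatures(m, array(0, c(12, 12, 3, 0)))
  expect_equal(dim(featureMatrix(e)), c(0L, 7L))
})

test_that("training contracts hold: no-op epochs, class checks, resizing", {
  cfg <- tiny_config(nClasses = 2L)
  m <- buildModel(cfg, seed = 5)
  set.seed(20)
  imgs <- array(runif(12 * 12 * 3 * 8), c(12, 12, 3, 8))
  y <- factor(rep(c("a", "b"), 4))
  m0 <- trainModel(m, imgs, y, trainConfig(maxEpochs = 0, seed = 1))
  expect_identical(m0@params, m@params)               # weights unchanged
  expect_equal(nrow(m0@history), 0L)                  # history empty
  expect_error(trainModel(m, imgs, factor(rep("a", 8)),
                          trainConfig(maxEpochs = 1)), "two classes")
  # wrong spatial size: resized with a warning, same feature width
  big <- array(runif(20 * 20 * 3 * 2), c(20, 20, 3, 2))
  expect_warning(fs <- extractDeepFeatures(m, big), "resizing")
  expect_equal(ncol(featureMatrix(fs)), 7L)
})

test_that("engine gradients match finite differences through the full net", {
  cfg <- tiny_config(nClasses = 3L, inputSize = 9L)
  m <- buildModel(cfg, seed = 2)
  set.seed(1)
  x <- array(runif(9 * 9 * 3 * 3), c(9, 9, 3, 3))
  yIdx <- c(1L, 2L, 1L)
  lossfn <- function(model)
    fundusNCAR:::cross_entropy(
      fundusNCAR:::net_forward(model, x, "train")$probs, yIdx)
  fw <- fundusNCAR:::net_forward(m, x, "train")
  onehot <- matrix(0, 3, 3); onehot[cbind(yIdx, 1:3)] <- 1
  g <- fundusNCAR:::net_backward(m, (fw$probs - onehot) / 3, fw$caches)
  eps <- 1e-5
  paths <- list(list("stem", "W"), list("blocks", 1L, "conv1", "W"),
                list("blocks", 1L, "bn1", "gamma"),
                list("blocks", 2L, "conv2", "W"),
                list("blocks", 2L, "proj", "W"),
                list("lstm", "W"), list("fc1", "W"), list("fc2", "W"),
                list("fc2", "b"))
  get_leaf <- function(tree, pt) { for (k in pt) tree <- tree[[k]]; tree }
  set_leaf <- function(tree, pt, val) {
    if (length(pt) == 1L) { tree[[pt[[1L]]]] <- val; return(tree) }
    tree[[pt[[1L]]]] <- set_leaf(tree[[pt[[1L]]]], pt[-1L], val)
    tree
  }
  set.seed(8)
  for (pt in paths) {
    leaf <- get_leaf(m@params, pt)
    gleaf <- get_leaf(g, pt)
    expect_gt(length(leaf), 0L)
    for (i in sample(length(leaf), 2)) {
      perturb <- function(delta) {
        lf <- leaf; lf[i] <- leaf[i] + delta
        mm <- m; mm@params <- set_leaf(m@params, pt, lf)
        lossfn(mm)
      }
      num <- (perturb(eps) - perturb(-eps)) / (2 * eps)
      # BN affine parameters shift a whole channel, so many ReLU inputs
      # cross their kink inside the finite-difference interval; the
      # analytic subgradient is exact but the FD quotient is noisy there
      tol <- if (any(unlist(pt) %in% c("gamma", "beta"))) 5e-3
             else 1e-6 * max(1, abs(num))
      expect_lt(abs(num - gleaf[i]), tol)
    }
  }
})

test_that("training drives the loss down on a separable toy problem", {
  # bright-vs-dark 12px images are linearly separable; with a small step
  # the epoch losses should trend monotonically down
  set.seed(30)
  n <- 16
  imgs <- array(runif(12 * 12 * 3 * n, 0, 0.2), c(12, 12, 3, n))
  y <- factor(rep(c("dark", "bright"), each = n / 2))
  imgs[, , , y == "bright"] <- imgs[, , , y == "bright"] + 0.7
  m <- buildModel(tiny_config(nClasses = 2L), seed = 4)
  m <- trainModel(m, imgs, y, trainConfig(batchSize = 8, learningRate = 5e-3,
                                          maxEpochs = 10, seed = 2))
  expect_true(all(diff(m@history$loss) < 0.05))       # near-monotone decrease
  expect_lt(m@history$loss[10L], m@history$loss[1L])
  expect_gte(m@history$accuracy[10L], 0.9)
})

test_that("a small model separates two phantom classes", {
  ph <- generatePhantomImages(synthImageSpec(
    nPerClass = 20, classNames = c("Normal", "Cataract"), imageSize = 32,
    seed = 1))
  cfg <- modelConfig(nResidualBlocks = 2L, stemFilters = 8L,
                     blockFilters = c(16L, 16L), lstmUnits = 32L,
                     fc1Width = 64L, nClasses = 2L, inputSize = 32L)
  m <- buildModel(cfg, seed = 1)
  m <- trainModel(m, ph$images, ph$labels,
                  trainConfig(batchSize = 20, learningRate = 0.01,
                              maxEpochs = 10, seed = 1))
  expect_gte(max(m@history$accuracy), 0.95)
})
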
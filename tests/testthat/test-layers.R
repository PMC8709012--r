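test_that("batch normalisation matches direct arithmetic", {
  # constant batch: all standardised values are 0
  expect_equal(batchNormalize(c(5, 5, 5), alpha = 1, beta = 0), rep(0, 3))
  # zero scale annihilates the input
  expect_equal(batchNormalize(c(-2, 7, 1), alpha = 0, beta = 3), rep(3, 3))
  # hand-computed: mu = 2, population variance = 2/3, xhat = +-1.224745
  expect_equal(batchNormalize(c(1, 2, 3), alpha = 2, beta = 1, epsilon = 0),
               c(1 - 2 * sqrt(3 / 2), 1, 1 + 2 * sqrt(3 / 2)),
               tolerance = 1e-12)
  expect_error(batchNormalize(numeric()), "at least one")
})

test_that("batch normalisation standardises random batches", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(50, mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    z <- batchNormalize(x, alpha = 1, beta = 0, epsilon = 0)
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(mean(z^2) - 1), 1e-6)     # population variance 1
  }
})

test_that("relu, sigmoid and derivative follow their closed forms", {
  expect_equal(relu(c(-3, 0, 2.5)), c(0, 0, 2.5))
  expect_equal(dim(relu(matrix(c(-1, 2), 1))), c(1L, 2L))
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 1 / (1 + exp(-1)))
  expect_equal(sigmoidDerivative(0), 0.25)
  set.seed(3)
  z <- rnorm(20)
  expect_equal(sigmoidDerivative(z), sigmoid(z) * (1 - sigmoid(z)))
})

test_that("softmax is a stable, shift-invariant probability map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(softmax(c(1, 2, 3)),
               exp(1:3) / sum(exp(1:3)), tolerance = 1e-12)
  expect_error(softmax(numeric()), "non-empty")
  set.seed(7)
  for (rep in 1:10) {
    a <- rnorm(sample(2:64, 1), sd = 10)
    s <- softmax(a)
    expect_lt(abs(sum(s) - 1), 1e-12)
    expect_lt(max(abs(s - softmax(a + 123.45))), 1e-12)  # shift invariance
    expect_true(all(s > 0))
  }
  # extreme scores do not overflow
  expect_equal(softmax(c(1e4, 0))[1L], 1)
})

test_that("lstm step reproduces the gated update equations", {
  zeroP <- lstmParams(Wf = matrix(0, 2, 5), Wi = matrix(0, 2, 5),
                      Wc = matrix(0, 2, 5), Wo = matrix(0, 2, 5),
                      bf = c(0, 0), bi = c(0, 0), bc = c(0, 0), bo = c(0, 0))
  # all-zero parameters: gates 0.5, candidate 0, so C_t = 0 and h_t = 0
  s0 <- lstmStep(c(1, -2, 3), lstmState(c(0, 0), c(0, 0)), zeroP)
  g <- attr(s0, "gates")
  expect_equal(g$f, c(0.5, 0.5))
  expect_equal(g$i, c(0.5, 0.5))
  expect_equal(g$o, c(0.5, 0.5))
  expect_equal(g$Ctilde, c(0, 0))
  expect_equal(s0$C, c(0, 0))
  expect_equal(s0$h, c(0, 0))

  # with prior cell state c: C_t = 0.5 c, h_t = 0.5 tanh(0.5 c)
  cc <- c(1.2, -0.4)
  s1 <- lstmStep(c(0, 0, 0), lstmState(c(0, 0), cc), zeroP)
  expect_equal(s1$C, 0.5 * cc)
  expect_equal(s1$h, 0.5 * tanh(0.5 * cc))

  # scalar unit, unit weights: hand evaluation of the update equations
  oneP <- lstmParams(Wf = matrix(1, 1, 2), Wi = matrix(1, 1, 2),
                     Wc = matrix(1, 1, 2), Wo = matrix(1, 1, 2),
                     bf = 0, bi = 0, bc = 0, bo = 0)
  s2 <- lstmStep(1, lstmState(0, 0), oneP)
  sig1 <- 1 / (1 + exp(-1))
  Cexp <- sig1 * tanh(1)
  expect_equal(s2$C, Cexp, tolerance = 1e-10)
  expect_equal(s2$h, sig1 * tanh(Cexp), tolerance = 1e-10)
  expect_equal(round(s2$C, 5), 0.55677)
  expect_equal(round(s2$h, 5), 0.36961)
})

test_that("lstm step validates shapes and bounds its outputs", {
  p <- lstmParams(Wf = matrix(0.3, 2, 5), Wi = matrix(-0.2, 2, 5),
                  Wc = matrix(0.1, 2, 5), Wo = matrix(0.2, 2, 5),
                  bf = c(0, 1), bi = c(0, 0), bc = c(1, 0), bo = c(0, 0))
  expect_error(lstmStep(c(1, 2), lstmState(c(0, 0), c(0, 0)), p), "inputDim")
  expect_error(lstmStep(c(1, 2, 3), lstmState(0, 0), p), "units")
  expect_error(lstmParams(Wf = matrix(0, 2, 5), Wi = matrix(0, 2, 4),
                          Wc = matrix(0, 2, 5), Wo = matrix(0, 2, 5),
                          bf = c(0, 0), bi = c(0, 0), bc = c(0, 0),
                          bo = c(0, 0)), "Wi")
  set.seed(12)
  st <- lstmState(runif(2, -0.5, 0.5), rnorm(2))
  for (rep in 1:10) {
    st <- lstmStep(rnorm(3), st, p)
    g <- attr(st, "gates")
    expect_true(all(g$f > 0 & g$f < 1))
    expect_true(all(g$i > 0 & g$i < 1))
    expect_true(all(g$o > 0 & g$o < 1))
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("engine layers agree with the scalar reference ops", {
  set.seed(99)
  # batch normalisation: one channel, batch of scalars
  for (rep in 1:5) {
    x <- rnorm(40, 2, 3)
    alpha <- runif(1, 0.5, 2); beta <- rnorm(1)
    eng <- fundusNCAR:::bn_forward(array(x, c(1, 1, 40, 1)), gamma = alpha,
                                   beta = beta,
                                   running = list(mean = 0, var = 1),
                                   mode = "train")
    expect_lt(max(abs(as.numeric(eng$out) -
                      batchNormalize(x, alpha, beta, 1e-5))), 1e-5)
  }
  # softmax head: column-wise engine vs reference per column
  z <- matrix(rnorm(12, sd = 4), 3, 4)
  sm <- fundusNCAR:::softmax_cols(z)
  for (j in 1:4) expect_lt(max(abs(sm[, j] - softmax(z[, j]))), 1e-12)
  # LSTM: one fused engine step vs the reference cell, random parameters
  U <- 3L; D <- 4L
  for (rep in 1:5) {
    Wf <- matrix(rnorm(U * (U + D), sd = 0.4), U)
    Wi <- matrix(rnorm(U * (U + D), sd = 0.4), U)
    Wc <- matrix(rnorm(U * (U + D), sd = 0.4), U)
    Wo <- matrix(rnorm(U * (U + D), sd = 0.4), U)
    bf <- rnorm(U); bi <- rnorm(U); bc <- rnorm(U); bo <- rnorm(U)
    x1 <- rnorm(D); x2 <- rnorm(D)
    Wstack <- rbind(Wf, Wi, Wc, Wo)
    bstack <- c(bf, bi, bc, bo)
    seqArr <- array(c(x1, x2), c(D, 1, 2))
    eng <- fundusNCAR:::lstm_forward(seqArr, Wstack, bstack)
    ref1 <- lstmStep(x1, lstmState(rep(0, U), rep(0, U)),
                     lstmParams(Wf, Wi, Wc, Wo, bf, bi, bc, bo))
    ref2 <- lstmStep(x2, ref1, lstmParams(Wf, Wi, Wc, Wo, bf, bi, bc, bo))
    expect_lt(max(abs(as.numeric(eng$out) - ref2$h)), 1e-5)
  }
})
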
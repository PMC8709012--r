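# The residual CNN+LSTM feature extractor: construction, training with
# SGDM + cross-entropy, and deep-feature extraction from the first fully
# connected layer.

#' Residual CNN+LSTM network object
#'
#' Created by [buildModel()]; holds the architecture configuration, all
#' learnable parameters, batch-normalisation running statistics and the
#' training history.
#'
#' @slot config the [ModelConfig-class].
#' @slot params nested list of learnable arrays.
#' @slot state batch-normalisation running means/variances.
#' @slot trained whether [trainModel()] has updated the weights.
#' @slot classLevels class labels the softmax head maps to.
#' @slot history per-epoch loss/accuracy data frame.
#' @name RCNNLSTM-class
#' @aliases RCNNLSTM
#' @exportClass RCNNLSTM
setClass("RCNNLSTM",
  representation(config = "ModelConfig", params = "list", state = "list",
                 trained = "logical", classLevels = "character",
                 history = "data.frame"))

setMethod("show", "RCNNLSTM", function(object) {
  cat(sprintf("RCNNLSTM (%s): %s, %s parameters\n",
              object@config@variant,
              if (object@trained) "trained" else "initialized",
              format(countParams(object), big.mark = ",")))
  show(object@config)
})

uses_skip <- function(config) config@variant %in% c("rcnn", "rcnn_lstm")
uses_lstm <- function(config) config@variant %in% c("cnn_lstm", "rcnn_lstm")

# Per-block stride schedule: spatial stride 2 on every second block.
block_strides <- function(nBlocks) ifelse(seq_len(nBlocks) %% 2L == 0L, 2L, 1L)

# Spatial sizes after each block (no validation).
sim_sizes <- function(inputSize, k, strides) {
  pad <- k %/% 2L
  s <- inputSize
  vapply(strides, function(st) {
    s <<- conv_out_size(s, k, st, pad)
    s
  }, integer(1))
}

# Simulate the spatial sizes through the stack; error if any collapses.
# The LSTM variants additionally need at least 2 rows in the final map to
# form a non-trivial sequence.
plan_sizes <- function(config) {
  strides <- block_strides(config@nResidualBlocks)
  minFinal <- if (uses_lstm(config)) 2L else 1L
  sizes <- sim_sizes(config@inputSize, config@kernelSize, strides)
  if (any(sizes < 1L) || sizes[length(sizes)] < minFinal) {
    minSize <- 2L
    repeat {
      s2 <- sim_sizes(minSize, config@kernelSize, strides)
      if (all(s2 >= 1L) && s2[length(s2)] >= minFinal) break
      minSize <- minSize + 1L
    }
    stop(sprintf(
      "inputSize %d too small for the downsampling schedule; minimum is %d",
      config@inputSize, minSize))
  }
  list(sizes = sizes, final = sizes[length(sizes)])
}

init_conv <- function(kh, kw, inC, outC) {
  K <- kh * kw * inC
  list(W = matrix(stats::rnorm(K * outC, sd = sqrt(2 / K)), K, outC),
       b = numeric(outC))
}

init_bn <- function(C) list(gamma = rep(1, C), beta = numeric(C))

#' Assemble a (residual) CNN or CNN+LSTM network
#'
#' Builds the computation graph: convolutional stem, `nResidualBlocks`
#' blocks of conv-BN-ReLU-conv-BN (with a skip connection and post-add
#' ReLU for the `rcnn*` variants; a 1x1 projection on the skip path when
#' shape changes), stride-2 downsampling on every second block, then
#' either row-wise unfolding into an LSTM (`*_lstm` variants) or
#' flattening, followed by FC(fc1Width) -> ReLU -> dropout ->
#' FC(nClasses) -> softmax.  Weights are seeded, so construction is
#' reproducible.
#'
#' @param config a [modelConfig()] object.
#' @param seed integer seed for weight initialisation.
#' @return an [RCNNLSTM-class] object (untrained).
#' @examples
#' m <- buildModel(modelConfig(nResidualBlocks = 1, blockFilters = 4L,
#'   stemFilters = 4L, lstmUnits = 8L, fc1Width = 16L, nClasses = 2,
#'   inputSize = 32L))
#' m
#' @export
buildModel <- function(config, seed = 1L) {
  validObject(config)
  plan <- plan_sizes(config)
  k <- config@kernelSize; pad <- k %/% 2L
  strides <- block_strides(config@nResidualBlocks)
  with_seed(stream_seed(seed, "model"), {
    params <- list(stem = init_conv(k, k, 3L, config@stemFilters),
                   bn_stem = init_bn(config@stemFilters),
                   blocks = list())
    state <- list(bn_stem = list(mean = numeric(config@stemFilters),
                                 var = rep(1, config@stemFilters)),
                  blocks = list())
    inC <- config@stemFilters
    for (i in seq_len(config@nResidualBlocks)) {
      outC <- config@blockFilters[i]
      blk <- list(conv1 = init_conv(k, k, inC, outC), bn1 = init_bn(outC),
                  conv2 = init_conv(k, k, outC, outC), bn2 = init_bn(outC))
      st <- list(bn1 = list(mean = numeric(outC), var = rep(1, outC)),
                 bn2 = list(mean = numeric(outC), var = rep(1, outC)))
      if (uses_skip(config) && (inC != outC || strides[i] != 1L)) {
        blk$proj <- init_conv(1L, 1L, inC, outC)
        blk$bnp <- init_bn(outC)
        st$bnp <- list(mean = numeric(outC), var = rep(1, outC))
      }
      params$blocks[[i]] <- blk
      state$blocks[[i]] <- st
      inC <- outC
    }
    if (uses_lstm(config)) {
      U <- config@lstmUnits
      D <- plan$final * inC                     # one row: W * C activations
      lim <- 1 / sqrt(U)
      W <- matrix(stats::runif(4L * U * (U + D), -lim, lim), 4L * U, U + D)
      b <- numeric(4L * U)
      b[seq_len(U)] <- 1                        # forget-gate bias
      params$lstm <- list(W = W, b = b)
      featD <- U
    } else {
      featD <- plan$final * plan$final * inC
    }
    params$fc1 <- list(
      W = matrix(stats::rnorm(config@fc1Width * featD,
                              sd = sqrt(2 / featD)), config@fc1Width, featD),
      b = numeric(config@fc1Width))
    params$fc2 <- list(
      W = matrix(stats::rnorm(config@nClasses * config@fc1Width,
                              sd = sqrt(1 / config@fc1Width)),
                 config@nClasses, config@fc1Width),
      b = numeric(config@nClasses))
    new("RCNNLSTM", config = config, params = params, state = state,
        trained = FALSE, classLevels = character(),
        history = data.frame(epoch = integer(), loss = numeric(),
                             accuracy = numeric()))
  })
}

#' Number of learnable parameters
#'
#' @param model an [RCNNLSTM-class] object.
#' @return integer count of all weights and biases (including the batch
#'   normalisation scale/shift pairs).
#' @export
countParams <- function(model) {
  stopifnot(is(model, "RCNNLSTM"))
  as.integer(tree_n_params(model@params))
}

#' Unfold a feature map into an LSTM input sequence
#'
#' Each of the `H` rows of an `H x W x C` activation map becomes one
#' timestep of length `W * C`, with the column index varying fastest and
#' the channel slowest.
#'
#' @param featureMap numeric array `H x W x C`.
#' @return numeric matrix with `H` rows (timesteps) and `W * C` columns.
#' @examples
#' m <- array(1:8, c(2, 2, 2))
#' foldToSequence(m)
#' @export
foldToSequence <- function(featureMap) {
  d <- dim(featureMap)
  if (length(d) != 3L) stop("featureMap must be an H x W x C array")
  s <- fold_map_to_seq(array(featureMap, c(d[1L], d[2L], 1L, d[3L])))
  t(matrix(s, d[2L] * d[3L], d[1L]))
}

#' Refold a sequence back into a feature map
#'
#' Inverse of [foldToSequence()].
#'
#' @param seqMat matrix of `H` timesteps by `W * C` features.
#' @param W,C spatial width and channel count of the original map.
#' @return numeric array `H x W x C`.
#' @export
unfoldSequence <- function(seqMat, W, C) {
  H <- nrow(seqMat)
  if (ncol(seqMat) != W * C) stop("ncol(seqMat) must equal W * C")
  s <- array(t(seqMat), c(W * C, 1L, H))
  arr <- unfold_seq_to_map(s, H, W, 1L, C)
  array(arr, c(H, W, C))
}

# Full network forward pass.  Public image batches are (H, W, C, N);
# internally the engine layout (H, W, N, C) is used.  mode "train"
# records caches and updates BN running statistics; "infer" uses the
# stored statistics and no dropout.
net_forward <- function(model, x, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  cfg <- model@config
  p <- model@params; st <- model@state
  k <- cfg@kernelSize; pad <- k %/% 2L
  strides <- block_strides(cfg@nResidualBlocks)
  caches <- list()
  x <- aperm(x, c(1L, 2L, 4L, 3L))                    # -> (H, W, N, C)

  cv <- conv_forward(x, p$stem$W, p$stem$b, k, k, 1L, pad)
  bn <- bn_forward(cv$out, p$bn_stem$gamma, p$bn_stem$beta, st$bn_stem, mode)
  st$bn_stem <- bn$running
  rl <- relu_forward(bn$out)
  caches$stem <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
  cur <- rl$out

  caches$blocks <- vector("list", cfg@nResidualBlocks)
  for (i in seq_len(cfg@nResidualBlocks)) {
    blk <- p$blocks[[i]]; bst <- st$blocks[[i]]
    cc <- list()
    inMap <- cur
    c1 <- conv_forward(inMap, blk$conv1$W, blk$conv1$b, k, k, strides[i], pad)
    b1 <- bn_forward(c1$out, blk$bn1$gamma, blk$bn1$beta, bst$bn1, mode)
    bst$bn1 <- b1$running
    r1 <- relu_forward(b1$out)
    c2 <- conv_forward(r1$out, blk$conv2$W, blk$conv2$b, k, k, 1L, pad)
    b2 <- bn_forward(c2$out, blk$bn2$gamma, blk$bn2$beta, bst$bn2, mode)
    bst$bn2 <- b2$running
    cc$conv1 <- c1$cache; cc$bn1 <- b1$cache; cc$relu1 <- r1$cache
    cc$conv2 <- c2$cache; cc$bn2 <- b2$cache
    if (uses_skip(cfg)) {
      if (!is.null(blk$proj)) {
        pj <- conv_forward(inMap, blk$proj$W, blk$proj$b, 1L, 1L,
                           strides[i], 0L)
        bp <- bn_forward(pj$out, blk$bnp$gamma, blk$bnp$beta, bst$bnp, mode)
        bst$bnp <- bp$running
        sc <- bp$out
        cc$proj <- pj$cache; cc$bnp <- bp$cache
      } else sc <- inMap
      added <- b2$out + sc
    } else added <- b2$out
    r2 <- relu_forward(added)
    cc$relu2 <- r2$cache
    cur <- r2$out
    caches$blocks[[i]] <- cc
    st$blocks[[i]] <- bst
  }

  d <- dim(cur)                                       # (H, W, N, C)
  caches$mapDim <- d
  if (uses_lstm(cfg)) {
    seqArr <- fold_map_to_seq(cur)
    lf <- lstm_forward(seqArr, p$lstm$W, p$lstm$b)
    feat <- lf$out
    caches$lstm <- lf
  } else {
    feat <- flatten_map(cur)
  }

  f1 <- fc_forward(feat, p$fc1$W, p$fc1$b)
  fc1pre <- f1$out                                    # deep features (pre-ReLU)
  r3 <- relu_forward(fc1pre)
  dp <- dropout_forward(r3$out, cfg@dropoutRate, mode)
  f2 <- fc_forward(dp$out, p$fc2$W, p$fc2$b)
  probs <- softmax_cols(f2$out)
  caches$fc1 <- f1$cache; caches$relu3 <- r3$cache; caches$drop <- dp$cache
  caches$fc2 <- f2$cache

  list(probs = probs, fc1pre = fc1pre, caches = caches, state = st)
}

# Full backward pass from the softmax cross-entropy gradient (dlogits).
net_backward <- function(model, dlogits, caches) {
  cfg <- model@config
  p <- model@params
  g <- tree_zeros_like(p)

  fb2 <- fc_backward(dlogits, caches$fc2, p$fc2$W)
  g$fc2$W <- fb2$dW; g$fc2$b <- fb2$db
  dd <- dropout_backward(fb2$dx, caches$drop)
  dr3 <- relu_backward(dd, caches$relu3)
  fb1 <- fc_backward(dr3, caches$fc1, p$fc1$W)
  g$fc1$W <- fb1$dW; g$fc1$b <- fb1$db
  dfeat <- fb1$dx

  d <- caches$mapDim                                  # (H, W, N, C)
  if (uses_lstm(cfg)) {
    lb <- lstm_backward(dfeat, caches$lstm, p$lstm$W)
    g$lstm$W <- lb$dW; g$lstm$b <- lb$db
    dcur <- unfold_seq_to_map(lb$dseq, d[1L], d[2L], d[3L], d[4L])
  } else {
    dcur <- unflatten_map(dfeat, d[1L], d[2L], d[3L], d[4L])
  }

  for (i in rev(seq_len(cfg@nResidualBlocks))) {
    cc <- caches$blocks[[i]]
    blk <- p$blocks[[i]]
    dadd <- relu_backward(dcur, cc$relu2)
    db2 <- bn_backward(dadd, cc$bn2)
    g$blocks[[i]]$bn2$gamma <- db2$dgamma
    g$blocks[[i]]$bn2$beta <- db2$dbeta
    cb2 <- conv_backward(db2$dx, cc$conv2)
    g$blocks[[i]]$conv2$W <- cb2$dW; g$blocks[[i]]$conv2$b <- cb2$db
    dr1 <- relu_backward(cb2$dx, cc$relu1)
    db1 <- bn_backward(dr1, cc$bn1)
    g$blocks[[i]]$bn1$gamma <- db1$dgamma
    g$blocks[[i]]$bn1$beta <- db1$dbeta
    cb1 <- conv_backward(db1$dx, cc$conv1)
    g$blocks[[i]]$conv1$W <- cb1$dW; g$blocks[[i]]$conv1$b <- cb1$db
    dIn <- cb1$dx
    if (uses_skip(cfg)) {
      if (!is.null(blk$proj)) {
        dbp <- bn_backward(dadd, cc$bnp)
        g$blocks[[i]]$bnp$gamma <- dbp$dgamma
        g$blocks[[i]]$bnp$beta <- dbp$dbeta
        cbp <- conv_backward(dbp$dx, cc$proj)
        g$blocks[[i]]$proj$W <- cbp$dW; g$blocks[[i]]$proj$b <- cbp$db
        dIn <- dIn + cbp$dx
      } else {
        dIn <- dIn + dadd
      }
    }
    dcur <- dIn
  }

  dr0 <- relu_backward(dcur, caches$stem$relu)
  db0 <- bn_backward(dr0, caches$stem$bn)
  g$bn_stem$gamma <- db0$dgamma
  g$bn_stem$beta <- db0$dbeta
  cb0 <- conv_backward(db0$dx, caches$stem$conv)
  g$stem$W <- cb0$dW; g$stem$b <- cb0$db
  g
}

# Bilinear resize of an (H, W, C, N) image batch to side x side.
resize_images <- function(x, side) {
  d <- dim(x)
  if (d[1L] == side && d[2L] == side) return(x)
  sy <- (d[1L] - 1) / (side - 1); sx <- (d[2L] - 1) / (side - 1)
  yy <- (seq_len(side) - 1) * sy + 1
  xx <- (seq_len(side) - 1) * sx + 1
  y0 <- pmin(floor(yy), d[1L] - 1L); x0 <- pmin(floor(xx), d[2L] - 1L)
  wy <- yy - y0; wx <- xx - x0
  out <- array(0, c(side, side, d[3L], d[4L]))
  for (ch in seq_len(d[3L])) for (n in seq_len(d[4L])) {
    m <- x[, , ch, n]
    m00 <- m[y0, x0]; m01 <- m[y0, x0 + 1L]
    m10 <- m[y0 + 1L, x0]; m11 <- m[y0 + 1L, x0 + 1L]
    out[, , ch, n] <-
      outer(1 - wy, 1 - wx) * m00 + outer(1 - wy, wx) * m01 +
      outer(wy, 1 - wx) * m10 + outer(wy, wx) * m11
  }
  out
}

check_images <- function(model, images) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  s <- model@config@inputSize
  if (dim(images)[1L] != s || dim(images)[2L] != s) {
    warning(sprintf("resizing images from %dx%d to the model input %dx%d",
                    dim(images)[1L], dim(images)[2L], s, s))
    images <- resize_images(images, s)
  }
  images
}

#' Train the network with SGDM and cross-entropy
#'
#' Runs mini-batch stochastic gradient descent with momentum on the
#' softmax cross-entropy loss.  Shuffling, dropout and therefore the whole
#' trajectory are governed by the seed in `tc`, so training is
#' reproducible.  With `maxEpochs = 0` the weights are returned unchanged
#' and the history is empty.
#'
#' @param model an [RCNNLSTM-class] from [buildModel()].
#' @param images array `H x W x 3 x N` with values in `[0, 1]` (resized
#'   with a warning if the spatial size differs from the model input).
#' @param labels factor (or coercible) of length `N`; at least two classes.
#' @param tc a [trainConfig()] object.
#' @param verbose print per-epoch progress.
#' @return the trained [RCNNLSTM-class]; its `history` slot holds one row
#'   per epoch with the mean training loss and accuracy.
#' @export
trainModel <- function(model, images, labels, tc = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "RCNNLSTM"), is(tc, "TrainConfig"))
  validObject(tc)
  images <- check_images(model, images)
  y <- as_label_factor(labels, dim(images)[4L])
  if (nlevels(y) < 2L)
    stop("training requires at least two classes in 'labels'")
  if (nlevels(y) != model@config@nClasses)
    stop(sprintf("model head has %d classes but labels have %d levels",
                 model@config@nClasses, nlevels(y)))
  model@classLevels <- levels(y)
  yIdx <- as.integer(y)
  n <- dim(images)[4L]
  if (tc@maxEpochs == 0L) return(model)

  vel <- tree_zeros_like(model@params)
  hist <- data.frame(epoch = seq_len(tc@maxEpochs), loss = NA_real_,
                     accuracy = NA_real_)
  with_seed(stream_seed(tc@seed, "train"), {
    for (ep in seq_len(tc@maxEpochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tc@batchSize)
      epLoss <- 0; epAcc <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + tc@batchSize - 1L, n)]
        xb <- images[, , , idx, drop = FALSE]
        yb <- yIdx[idx]
        fw <- net_forward(model, xb, "train")
        model@state <- fw$state
        loss <- cross_entropy(fw$probs, yb)
        pred <- max.col(t(fw$probs))
        epLoss <- epLoss + loss * length(idx)
        epAcc <- epAcc + sum(pred == yb)
        onehot <- matrix(0, model@config@nClasses, length(idx))
        onehot[cbind(yb, seq_along(yb))] <- 1
        dlogits <- (fw$probs - onehot) / length(idx)
        grads <- net_backward(model, dlogits, fw$caches)
        upd <- tree_sgdm(model@params, grads, vel, tc@learningRate,
                         tc@momentum)
        model@params <- upd$p; vel <- upd$v
      }
      hist$loss[ep] <- epLoss / n
      hist$accuracy[ep] <- epAcc / n
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.4f", ep,
                        hist$loss[ep], hist$accuracy[ep]))
    }
  })
  model@trained <- TRUE
  model@history <- hist
  model
}

#' Extract deep features from the first fully connected layer
#'
#' Runs the network in inference mode (batch-normalisation running
#' statistics, no dropout) and returns the pre-ReLU activations of the
#' first fully connected layer, one row per image.
#'
#' @param model an [RCNNLSTM-class] (trained or freshly initialised).
#' @param images array `H x W x 3 x N` (resized with a warning on size
#'   mismatch); `N = 0` yields a 0-row matrix.
#' @param sampleIds optional identifiers for the rows.
#' @param batchSize images per forward pass.
#' @return a [DeepFeatureSet-class] with an `N x fc1Width` matrix.
#' @export
extractDeepFeatures <- function(model, images, sampleIds = NULL,
                                batchSize = 64L) {
  stopifnot(is(model, "RCNNLSTM"))
  if (is.null(images) ||
      (length(dim(images)) == 4L && dim(images)[4L] == 0L)) {
    return(new("DeepFeatureSet",
               matrix = matrix(0, 0L, model@config@fc1Width),
               sampleIds = character(), source = "fc1 (pre-ReLU)"))
  }
  images <- check_images(model, images)
  n <- dim(images)[4L]
  out <- matrix(0, n, model@config@fc1Width)
  for (s0 in seq(1L, n, by = batchSize)) {
    idx <- s0:min(s0 + batchSize - 1L, n)
    fw <- net_forward(model, images[, , , idx, drop = FALSE], "infer")
    out[idx, ] <- t(fw$fc1pre)
  }
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  if (is.null(sampleIds)) sampleIds <- sprintf("sample_%04d", seq_len(n))
  new("DeepFeatureSet", matrix = out, sampleIds = as.character(sampleIds),
      source = sprintf("RCNNLSTM(%s) fc1 (pre-ReLU)", model@config@variant))
}

#' Class probabilities from the softmax head
#'
#' @param model a trained [RCNNLSTM-class].
#' @param images array `H x W x 3 x N`.
#' @param batchSize images per forward pass.
#' @return an `N x nClasses` matrix of softmax probabilities.
#' @export
predictModel <- function(model, images, batchSize = 64L) {
  stopifnot(is(model, "RCNNLSTM"))
  images <- check_images(model, images)
  n <- dim(images)[4L]
  out <- matrix(0, n, model@config@nClasses)
  for (s0 in seq(1L, n, by = batchSize)) {
    idx <- s0:min(s0 + batchSize - 1L, n)
    fw <- net_forward(model, images[, , , idx, drop = FALSE], "infer")
    out[idx, ] <- t(fw$probs)
  }
  if (length(model@classLevels)) colnames(out) <- model@classLevels
  out
}
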
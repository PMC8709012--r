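# Vectorised CPU neural-network engine: 2-D convolution by shifted-slice
# accumulation, spatial batch normalisation, LSTM with backpropagation
# through time, fully connected layers, dropout and a softmax
# cross-entropy head.
#
# All spatial activations use the internal layout (H, W, N, C): with the
# channel axis last, the column-major reshape to an (H*W*N) x C matrix is
# free, so batch normalisation and the per-kernel-offset convolution
# slices need no transposition.  Convolution weights are stored as a
# (kh*kw*C) x F matrix whose rows are grouped by kernel offset (column
# offset major, row offset within, input channel innermost).
#
# The scalar reference ops in layers.R are the independent check on this
# code; the test suite verifies agreement to 1e-5 on random inputs.

conv_out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# Row indices (into an Hp*Wp-row matrix) of the strided window slice for
# one kernel offset.
offset_rows <- function(di, dj, stride, oh, ow, Hp) {
  ridx <- seq(di, by = stride, length.out = oh)
  cidx <- seq(dj, by = stride, length.out = ow)
  as.vector(outer(ridx, (cidx - 1L) * Hp, "+"))
}

# Forward convolution on (H, W, N, C) input; returns (oh, ow, N, F).
# The padded input is held as an (Hp*Wp) x (N*C) matrix so every kernel
# offset's window is a plain row subset.
conv_forward <- function(x, W, b, kh, kw, stride, pad) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; N <- d[3L]; C <- d[4L]
  oh <- conv_out_size(H, kh, stride, pad)
  ow <- conv_out_size(Wd, kw, stride, pad)
  if (oh < 1L || ow < 1L) stop("convolution input too small for kernel")
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  if (pad > 0L) {
    xpm <- matrix(0, Hp * Wp, N * C)
    inRows <- as.vector(outer(pad + seq_len(H), (pad + seq_len(Wd) - 1L) * Hp,
                              "+"))
    dim(x) <- c(H * Wd, N * C)
    xpm[inRows, ] <- x
  } else {
    xpm <- x
    dim(xpm) <- c(Hp * Wp, N * C)
    inRows <- seq_len(Hp * Wp)
  }
  P <- oh * ow
  Y <- matrix(rep(b, each = P * N), P * N, length(b))
  bidx <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      sl <- xpm[offset_rows(di, dj, stride, oh, ow, Hp), , drop = FALSE]
      dim(sl) <- c(P * N, C)
      Y <- Y + sl %*% W[bidx * C + seq_len(C), , drop = FALSE]
      bidx <- bidx + 1L
    }
  }
  dim(Y) <- c(oh, ow, N, length(b))
  list(out = Y,
       cache = list(xpm = xpm, inRows = inRows, Hp = Hp, W = W, kh = kh,
                    kw = kw, stride = stride, pad = pad, inDim = d,
                    outHW = c(oh, ow)))
}

conv_backward <- function(dout, cache) {
  oh <- cache$outHW[1L]; ow <- cache$outHW[2L]
  d <- cache$inDim; N <- d[3L]; C <- d[4L]
  P <- oh * ow; stride <- cache$stride
  Fo <- dim(dout)[4L]
  dY <- dout; dim(dY) <- c(P * N, Fo)
  dW <- matrix(0, nrow(cache$W), Fo)
  db <- colSums(dY)
  dxpm <- matrix(0, nrow(cache$xpm), ncol(cache$xpm))
  bidx <- 0L
  for (dj in seq_len(cache$kw)) {
    for (di in seq_len(cache$kh)) {
      rows <- offset_rows(di, dj, stride, oh, ow, cache$Hp)
      wrows <- bidx * C + seq_len(C)
      sl <- cache$xpm[rows, , drop = FALSE]
      dim(sl) <- c(P * N, C)
      dW[wrows, ] <- crossprod(sl, dY)
      dsl <- tcrossprod(dY, cache$W[wrows, , drop = FALSE])
      dim(dsl) <- c(P, N * C)
      dxpm[rows, ] <- dxpm[rows, , drop = FALSE] + dsl
      bidx <- bidx + 1L
    }
  }
  dx <- dxpm[cache$inRows, , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# Spatial batch normalisation over (H, W, N) per channel; population (1/n)
# batch variance; running statistics for inference mode.
bn_forward <- function(x, gamma, beta, running, mode, eps = 1e-5,
                       momentum = 0.9) {
  d <- dim(x); C <- d[4L]; M <- d[1L] * d[2L] * d[3L]
  xm <- x; dim(xm) <- c(M, C)
  if (mode == "train") {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu                  # population variance
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean; v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(invstd, each = M)
  y <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  dim(y) <- d
  list(out = y, running = running,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, dims = d))
}

bn_backward <- function(dout, cache) {
  d <- cache$dims; C <- d[4L]; M <- d[1L] * d[2L] * d[3L]
  dy <- dout; dim(dy) <- c(M, C)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(cache$gamma, each = M)
  s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
  dx <- rep(cache$invstd / M, each = M) *
    (M * dxhat - rep(s1, each = M) - xhat * rep(s2, each = M))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_backward <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

fc_forward <- function(x, W, b) {
  list(out = W %*% x + b, cache = x)                  # x: (D, N)
}

fc_backward <- function(dout, x, W) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, x), db = rowSums(dout))
}

dropout_forward <- function(x, rate, mode) {
  if (mode != "train" || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# Fold an (H, W, N, C) activation map into an LSTM input sequence:
# T = H timesteps, each the row's W*C activations with the column index
# varying fastest, then the channel.  Returns array (W*C, N, T).
fold_map_to_seq <- function(x) {
  d <- dim(x)                                         # (H, W, N, C)
  s <- aperm(x, c(2L, 4L, 3L, 1L))                    # (W, C, N, H)
  dim(s) <- c(d[2L] * d[4L], d[3L], d[1L])
  s
}

unfold_seq_to_map <- function(s, H, W, N, C) {
  dim(s) <- c(W, C, N, H)
  aperm(s, c(4L, 1L, 3L, 2L))                         # (H, W, N, C)
}

# Per-image column-major flatten of (H, W, C): returns (H*W*C, N).
flatten_map <- function(x) {
  d <- dim(x)                                         # (H, W, N, C)
  f <- aperm(x, c(1L, 2L, 4L, 3L))                    # (H, W, C, N)
  dim(f) <- c(d[1L] * d[2L] * d[4L], d[3L])
  f
}

unflatten_map <- function(f, H, W, N, C) {
  dim(f) <- c(H, W, C, N)
  aperm(f, c(1L, 2L, 4L, 3L))
}

# Single fused LSTM over a sequence; gate order in the stacked weight
# matrix is (f, i, g, o).  Returns the last hidden state and BPTT caches.
lstm_forward <- function(seqArr, W, b) {
  D <- dim(seqArr)[1L]; N <- dim(seqArr)[2L]; Tn <- dim(seqArr)[3L]
  U <- length(b) %/% 4L
  h <- matrix(0, U, N); Cc <- matrix(0, U, N)
  caches <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(seqArr[, , t], D, N)
    hx <- rbind(h, xt)                                # (U + D, N)
    z <- W %*% hx + b
    f <- 1 / (1 + exp(-z[seq_len(U), , drop = FALSE]))
    i <- 1 / (1 + exp(-z[U + seq_len(U), , drop = FALSE]))
    g <- tanh(z[2L * U + seq_len(U), , drop = FALSE])
    o <- 1 / (1 + exp(-z[3L * U + seq_len(U), , drop = FALSE]))
    Cprev <- Cc
    Cc <- f * Cprev + i * g
    tc <- tanh(Cc)
    h <- o * tc
    caches[[t]] <- list(hx = hx, f = f, i = i, g = g, o = o,
                        Cprev = Cprev, tc = tc)
  }
  list(out = h, caches = caches, U = U, D = D, Tn = Tn, N = N)
}

lstm_backward <- function(dh_last, fwd, W) {
  U <- fwd$U; D <- fwd$D; Tn <- fwd$Tn; N <- fwd$N
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(nrow(W))
  dseq <- array(0, c(D, N, Tn))
  dh <- dh_last; dC <- matrix(0, U, N)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$caches[[t]]
    do_ <- dh * cc$tc
    dC <- dC + dh * cc$o * (1 - cc$tc^2)
    df <- dC * cc$Cprev
    di <- dC * cc$g
    dg <- dC * cc$i
    dCprev <- dC * cc$f
    dz <- rbind(df * cc$f * (1 - cc$f),
                di * cc$i * (1 - cc$i),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + tcrossprod(dz, cc$hx)
    db <- db + rowSums(dz)
    dhx <- crossprod(W, dz)
    dh <- dhx[seq_len(U), , drop = FALSE]
    dseq[, , t] <- dhx[U + seq_len(D), , drop = FALSE]
    dC <- dCprev
  }
  list(dW = dW, db = db, dseq = dseq)
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# Mean cross-entropy of column-wise probabilities against integer labels.
cross_entropy <- function(probs, yIdx) {
  p <- probs[cbind(yIdx, seq_along(yIdx))]
  -mean(log(pmax(p, 1e-12)))
}

# --- parameter-tree helpers -----------------------------------------------

tree_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, tree_zeros_like)
  else { z <- p; z[] <- 0; z }
}

# SGD with momentum over a nested parameter list; returns updated params
# and velocities.
tree_sgdm <- function(params, grads, vel, lr, mu) {
  if (is.list(params)) {
    for (nm in names(params)) {
      r <- tree_sgdm(params[[nm]], grads[[nm]], vel[[nm]], lr, mu)
      params[[nm]] <- r$p; vel[[nm]] <- r$v
    }
    list(p = params, v = vel)
  } else {
    v <- mu * vel - lr * grads
    list(p = params + v, v = v)
  }
}

tree_n_params <- function(p) {
  if (is.list(p)) sum(vapply(p, tree_n_params, numeric(1))) else length(p)
}
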
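# Reference implementations of the elementary network layers.  These are
# deliberately simple scalar/vector formulations used to cross-check the
# vectorised network engine (see engine.R) in the test suite.

#' Batch normalisation of a numeric batch
#'
#' Normalises a batch to zero mean and (population) unit variance and then
#' applies the affine transform `y = alpha * xhat + beta`.  The variance is
#' the population (1/n) variance of the batch, and `epsilon` guards the
#' division.
#'
#' @param batch numeric vector (length >= 1).
#' @param alpha scale parameter.
#' @param beta shift parameter.
#' @param epsilon positive variance guard (default `1e-5`).
#' @return numeric vector of the same length as `batch`.
#' @examples
#' batchNormalize(c(1, 2, 3), alpha = 2, beta = 1, epsilon = 0)
#' @export
batchNormalize <- function(batch, alpha = 1, beta = 0, epsilon = 1e-5) {
  if (length(batch) < 1L) stop("batch must contain at least one value")
  stopifnot_scalar(alpha, "alpha")
  stopifnot_scalar(beta, "beta")
  if (!is.numeric(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  mu <- mean(batch)
  sigma2 <- mean((batch - mu)^2)     # population (1/n) variance
  xhat <- (batch - mu) / sqrt(sigma2 + epsilon)
  alpha * xhat + beta
}

#' Rectified linear unit
#'
#' @param x numeric vector or array.
#' @return `max(0, x)` elementwise, preserving shape.
#' @examples
#' relu(c(-3, 0, 2.5))
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Logistic sigmoid
#'
#' @param z numeric vector or array.
#' @return `1 / (1 + exp(-z))` elementwise.
#' @examples
#' sigmoid(0)
#' @export
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Derivative of the logistic sigmoid
#'
#' @param z numeric vector or array.
#' @return `sigmoid(z) * (1 - sigmoid(z))` elementwise.
#' @examples
#' sigmoidDerivative(0)  # 0.25
#' @export
sigmoidDerivative <- function(z) {
  s <- sigmoid(z)
  s * (1 - s)
}

#' Numerically stable softmax
#'
#' Maps a score vector to a probability vector via
#' `s_j = exp(a_j) / sum_k exp(a_k)`, computed with max-subtraction so
#' large scores do not overflow.  The result is invariant to adding a
#' constant to all scores.
#'
#' @param a numeric vector (length >= 1).
#' @return probability vector summing to 1.
#' @examples
#' softmax(c(1, 2, 3))
#' @export
softmax <- function(a) {
  if (length(a) < 1L) stop("softmax input must be non-empty")
  e <- exp(a - max(a))
  e / sum(e)
}

#' LSTM cell parameters
#'
#' Weight matrices act on the concatenation `[h_{t-1}, x_t]` (hidden state
#' first), so each matrix has shape `units x (units + inputDim)`.
#'
#' @param Wf,Wi,Wc,Wo forget/input/candidate/output weight matrices.
#' @param bf,bi,bc,bo bias vectors of length `units`.
#' @return a validated list of class `"lstm_params"`.
#' @export
lstmParams <- function(Wf, Wi, Wc, Wo, bf, bi, bc, bo) {
  Ws <- list(Wf = as.matrix(Wf), Wi = as.matrix(Wi), Wc = as.matrix(Wc),
             Wo = as.matrix(Wo))
  bs <- list(bf = as.numeric(bf), bi = as.numeric(bi), bc = as.numeric(bc),
             bo = as.numeric(bo))
  units <- nrow(Ws$Wf)
  for (nm in names(Ws))
    if (!identical(dim(Ws[[nm]]), dim(Ws$Wf)))
      stop(sprintf("weight matrix %s has shape %s; expected %s", nm,
                   paste(dim(Ws[[nm]]), collapse = "x"),
                   paste(dim(Ws$Wf), collapse = "x")))
  for (nm in names(bs))
    if (length(bs[[nm]]) != units)
      stop(sprintf("bias %s must have length %d", nm, units))
  if (ncol(Ws$Wf) <= units)
    stop("weight matrices must have units + inputDim columns")
  structure(c(Ws, bs, list(units = units, inputDim = ncol(Ws$Wf) - units)),
            class = "lstm_params")
}

#' LSTM cell state
#'
#' @param h hidden vector (elements in `(-1, 1)` after an update).
#' @param C cell-state vector of the same length.
#' @return a list of class `"lstm_state"`.
#' @export
lstmState <- function(h, C) {
  h <- as.numeric(h); C <- as.numeric(C)
  if (length(h) != length(C)) stop("h and C must have the same length")
  structure(list(h = h, C = C), class = "lstm_state")
}

#' One LSTM time step
#'
#' Applies the gated update: forget gate `f`, input gate `i` and output
#' gate `o` are sigmoids of affine maps of `[h_{t-1}, x_t]`; the candidate
#' cell state is a tanh of the same form; then
#' `C_t = f * C_{t-1} + i * Ctilde` and `h_t = o * tanh(C_t)` elementwise.
#'
#' @param x_t input vector of length `inputDim`.
#' @param state an [lstmState()] holding `h_{t-1}` and `C_{t-1}`.
#' @param params an [lstmParams()] object.
#' @return an [lstmState()] with the updated `h` and `C`, plus attributes
#'   `"gates"` (list `f`, `i`, `o`, `Ctilde`) for inspection.
#' @examples
#' p <- lstmParams(Wf = matrix(1, 1, 2), Wi = matrix(1, 1, 2),
#'                 Wc = matrix(1, 1, 2), Wo = matrix(1, 1, 2),
#'                 bf = 0, bi = 0, bc = 0, bo = 0)
#' lstmStep(1, lstmState(0, 0), p)
#' @export
lstmStep <- function(x_t, state, params) {
  if (!inherits(params, "lstm_params")) params <- do.call(lstmParams, params)
  if (!inherits(state, "lstm_state")) state <- do.call(lstmState, state)
  x_t <- as.numeric(x_t)
  if (length(x_t) != params$inputDim)
    stop(sprintf("x_t has length %d; weight matrices expect inputDim %d",
                 length(x_t), params$inputDim))
  if (length(state$h) != params$units)
    stop(sprintf("state has %d units; weight matrices expect %d",
                 length(state$h), params$units))
  hx <- c(state$h, x_t)                         # [h_{t-1}, x_t]
  f <- sigmoid(drop(params$Wf %*% hx) + params$bf)
  i <- sigmoid(drop(params$Wi %*% hx) + params$bi)
  Ctilde <- tanh(drop(params$Wc %*% hx) + params$bc)
  o <- sigmoid(drop(params$Wo %*% hx) + params$bo)
  C_t <- f * state$C + i * Ctilde
  h_t <- o * tanh(C_t)
  out <- lstmState(h_t, C_t)
  attr(out, "gates") <- list(f = f, i = i, o = o, Ctilde = Ctilde)
  out
}
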
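# Neighbourhood component analysis (NCA) feature weighting: per-feature
# weights w are fitted by gradient ascent on the regularised objective
#
#   F(w) = (1/n) sum_i P_i - lambda * sum_r w_r^2,
#
# where P_i is the probability that a stochastic nearest neighbour of
# sample i (drawn with kernel exp(-d_w/sigma) over all other samples)
# shares its class.  The distance is a weighted L1 with squared weights,
#   d_w(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr|,
# so the effective per-feature weight is non-negative and the penalty
# term matches the squared weights in the objective.

# Pairwise |x_ir - x_jr| stacked as an n^2 x p matrix (column r is the
# vectorised n x n absolute-difference matrix of feature r).
abs_diff_matrix <- function(X) {
  n <- nrow(X); p <- ncol(X)
  D <- matrix(0, n * n, p)
  for (r in seq_len(p)) D[, r] <- abs(outer(X[, r], X[, r], "-"))
  D
}

# Kernelised neighbour probabilities for given weights.  Returns the n x n
# matrix p_ij (rows sum to 1, diagonal 0) and P_i = sum_{j same class} p_ij.
nca_prob_matrix <- function(Dmat, y, w, sigma) {
  n <- as.integer(sqrt(nrow(Dmat)))
  d <- matrix(Dmat %*% (w * w), n, n) / sigma
  # subtract the row minimum over j != i for numerical stability
  diag(d) <- Inf
  m <- apply(d, 1L, min)
  m[!is.finite(m)] <- 0
  K <- exp(-(d - m))
  K[!is.finite(K)] <- 0                       # the Inf diagonal -> p_ii = 0
  rs <- rowSums(K)
  rs[rs == 0] <- 1                            # isolated row (cannot happen n>1)
  Pmat <- K / rs
  same <- outer(y, y, "==")
  list(p = Pmat, P = rowSums(Pmat * same))
}

#' Stochastic same-class neighbour probabilities
#'
#' Computes `p_ij = exp(-d_w(x_i, x_j)/sigma) / sum_{l != i}
#' exp(-d_w(x_i, x_l)/sigma)` with `p_ii = 0` and the weighted L1 distance
#' `d_w(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr|`, and returns
#' `P_i = sum_{j : y_j = y_i} p_ij`, the probability that a stochastic
#' neighbour of sample `i` has the same class.
#'
#' @param X numeric matrix (n x p).
#' @param y class labels of length n.
#' @param w feature weights of length p.
#' @param sigma positive kernel width.
#' @return numeric vector `P` of length n, each entry in `[0, 1]`.
#' @examples
#' X <- matrix(c(0, 0.1, 1), ncol = 1)
#' ncaProbabilities(X, c("A", "A", "B"), w = 1)
#' @export
ncaProbabilities <- function(X, y, w, sigma = 1) {
  X <- check_feature_matrix(X, y)
  if (nrow(X) < 2L) stop("need at least two samples")
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (length(w) != ncol(X)) stop("length(w) must equal ncol(X)")
  y <- as_label_factor(y, nrow(X))
  nca_prob_matrix(abs_diff_matrix(X), y, as.numeric(w), sigma)$P
}

resolve_lambda <- function(config, n) {
  if (is.null(config@lambdaReg)) 1 / n else config@lambdaReg
}

#' Regularised NCA objective
#'
#' `F(w) = (1/n) sum_i P_i - lambda * sum_r w_r^2`; see
#' [ncaProbabilities()] for `P_i`.
#'
#' @param X numeric matrix (n x p).
#' @param y class labels.
#' @param w feature weights.
#' @param config an [ncaConfig()]; supplies `lambda` (default `1/n`) and
#'   the kernel width.  Standardisation is *not* applied here; pass the
#'   matrix you want evaluated.
#' @return numeric scalar.
#' @export
ncaObjective <- function(X, y, w, config = ncaConfig()) {
  X <- check_feature_matrix(X, y)
  P <- ncaProbabilities(X, y, w, config@kernelWidth)
  mean(P) - resolve_lambda(config, nrow(X)) * sum(w^2)
}

# Shared analytic gradient given precomputed structures.
nca_gradient_core <- function(Dmat, y, w, sigma, lambda) {
  n <- length(y)
  pr <- nca_prob_matrix(Dmat, y, w, sigma)
  same <- outer(y, y, "==")
  B <- pr$p * pr$P - pr$p * same              # n x n coefficient matrix
  colSum <- as.numeric(crossprod(Dmat, as.vector(B)))
  (2 * w / (sigma * n)) * colSum - 2 * lambda * w
}

#' Analytic gradient of the NCA objective
#'
#' Differentiates `F(w)` with respect to each feature weight:
#' `dF/dw_r = (2 w_r / (sigma n)) * sum_i (P_i sum_l p_il D_ilr -
#' sum_{j in hits(i)} p_ij D_ijr) - 2 lambda w_r`, with
#' `D_ijr = |x_ir - x_jr|`.  Matches central finite differences of
#' [ncaObjective()].
#'
#' @inheritParams ncaObjective
#' @return numeric vector of length p.
#' @export
ncaGradient <- function(X, y, w, config = ncaConfig()) {
  X <- check_feature_matrix(X, y)
  y <- as_label_factor(y, nrow(X))
  nca_gradient_core(abs_diff_matrix(X), y, as.numeric(w),
                    config@kernelWidth, resolve_lambda(config, nrow(X)))
}

#' Fit NCA feature weights by gradient ascent
#'
#' Starts from all-ones weights (after optional z-scoring of the
#' features), ascends the regularised objective with backtracking:
#' whenever a step would decrease the objective the step size is halved
#' (and gently re-grown after accepted steps).  Stops when the relative
#' objective change falls below `tol` or after `maxIters` accepted steps.
#' The recorded objective trace is non-decreasing by construction.
#'
#' @param X numeric matrix (n x p), n >= 2.
#' @param y class labels with at least two classes.
#' @param config an [ncaConfig()].
#' @return an [NCAWeights-class] object.  The weights refer to the
#'   (optionally standardised) features.
#' @examples
#' tab <- generateFeatureTable(synthTableSpec(nSamples = 60, nFeatures = 5,
#'   nInformative = 2, effectSize = 4, seed = 3))
#' fit <- fitNCA(tab$X, tab$y, ncaConfig(maxIters = 30))
#' featureWeights(fit)
#' @export
fitNCA <- function(X, y, config = ncaConfig()) {
  validObject(config)
  X <- check_feature_matrix(X, y)
  if (nrow(X) < 2L) stop("need at least two samples")
  y <- as_label_factor(y, nrow(X))
  if (nlevels(y) < 2L)
    stop("single class: P_i trivially maximal; weights unidentified")
  if (config@standardize) X <- zscore_columns(X)
  n <- nrow(X); p <- ncol(X)
  lambda <- resolve_lambda(config, n)
  sigma <- config@kernelWidth
  Dmat <- abs_diff_matrix(X)

  objective <- function(w) {
    pr <- nca_prob_matrix(Dmat, y, w, sigma)
    mean(pr$P) - lambda * sum(w^2)
  }
  w <- rep(1, p)
  fObj <- objective(w)
  trace <- fObj
  step <- config@learningRate
  converged <- FALSE
  for (it in seq_len(config@maxIters)) {
    gr <- nca_gradient_core(Dmat, y, w, sigma, lambda)
    gnorm <- sqrt(sum(gr^2))
    if (gnorm < 1e-12) { converged <- TRUE; break }
    accepted <- FALSE
    for (bt in 1:30) {
      wNew <- w + step * gr
      fNew <- objective(wNew)
      if (fNew >= fObj) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    relChange <- abs(fNew - fObj) / max(abs(fObj), 1e-12)
    w <- wNew
    fObj <- fNew
    trace <- c(trace, fObj)
    step <- step * 1.1
    if (relChange < config@tol) { converged <- TRUE; break }
  }
  names(w) <- colnames(X)
  new("NCAWeights", w = w, objectiveTrace = trace, converged = converged,
      lambdaReg = lambda)
}

#' Threshold NCA weights into a keep-mask
#'
#' Keeps features whose weight is at least `threshold`; strictly smaller
#' weights are removed.
#'
#' @param w numeric weights or an [NCAWeights-class] object.
#' @param threshold weight threshold (default 0.0005).
#' @return logical keep-mask of the same length as the weights.  A mask
#'   with no survivors triggers a warning.
#' @examples
#' selectByWeight(c(0.0004, 0.0005, 0.1), 0.0005)
#' @export
selectByWeight <- function(w, threshold = 5e-4) {
  if (is(w, "NCAWeights")) w <- featureWeights(w)
  mask <- as.numeric(w) >= threshold
  if (!any(mask))
    warning("no feature weight reaches the threshold; empty selection")
  mask
}
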
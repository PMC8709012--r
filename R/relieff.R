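# ReliefF importance weighting.  For each reference instance R_i the k
# nearest same-class neighbours (hits) pull the weight of every feature
# down by their normalised difference, and the k nearest neighbours in
# each other class (misses) push it up, scaled by the class prior
# P(C) / (1 - P(class(R_i))):
#
#   W(a) <- W(a) - sum_j diff(a, R_i, H_j) / (m k)
#               + sum_{C != class(R_i)} P(C)/(1 - P(class(R_i)))
#                 * sum_j diff(a, R_i, M_j^C) / (m k)

#' Range-normalised feature difference
#'
#' `diff(a, u, v) = |u_a - v_a| / range_a` for numeric features, defined
#' as 0 when the feature's range is 0.
#'
#' @param u,v numeric vectors (instances), same length.
#' @param ranges per-feature ranges (`max - min` over the data).
#' @return numeric vector in `[0, 1]` per feature.
#' @examples
#' featureDiff(c(0, 0.25), c(1, 0.75), ranges = c(1, 1))
#' @export
featureDiff <- function(u, v, ranges) {
  if (length(u) != length(v) || length(u) != length(ranges))
    stop("u, v and ranges must have the same length")
  out <- abs(u - v)
  nz <- ranges > 0
  out[nz] <- out[nz] / ranges[nz]
  out[!nz] <- 0
  out
}

# k smallest entries of d (ties broken by lowest index), restricted to
# candidate indices `cand`; self-exclusion is the caller's job.
nearest_k <- function(d, cand, k) {
  if (!length(cand) || k < 1L) return(integer())
  ord <- cand[order(d[cand], cand)]
  utils::head(ord, k)
}

#' ReliefF feature-importance weights
#'
#' Weights start at 0 and are updated over `m` reference instances using
#' the k nearest hits and per-class nearest misses under Manhattan
#' distance on range-normalised features; neighbour ties are broken by
#' the lowest instance index.  With `mSamples = "all"` (the default)
#' every instance is used exactly once and the result is deterministic;
#' with `mSamples < n` the references are sampled with the configured
#' seed.  With range-normalised differences every weight lies in
#' `[-1, 1]`.
#'
#' @param X numeric matrix (n x p).
#' @param y class labels; every class must have at least 2 members.
#' @param config a [relieffConfig()]; `kNeighbors` is clipped (with a
#'   warning) to the smallest class size minus one when necessary.
#' @return a [ReliefFWeights-class] object.
#' @examples
#' X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
#' relieffWeights(X, c(0, 0, 1, 1), relieffConfig(kNeighbors = 1))
#' @export
relieffWeights <- function(X, y, config = relieffConfig()) {
  validObject(config)
  X <- check_feature_matrix(X, y)
  y <- as_label_factor(y, nrow(X))
  if (nlevels(y) < 2L) stop("need at least two classes")
  counts <- table(y)
  if (any(counts < 2L))
    stop("class ", sQuote(names(counts)[which(counts < 2L)[1L]]),
         " has fewer than 2 members; hits are undefined")
  n <- nrow(X); p <- ncol(X)
  k <- config@kNeighbors
  if (k > min(counts) - 1L) {
    k <- as.integer(min(counts) - 1L)
    warning(sprintf("kNeighbors clipped to %d (smallest class size - 1)", k))
  }

  rng <- apply(X, 2L, function(col) diff(range(col)))
  Xn <- X
  nz <- rng > 0
  Xn[, nz] <- sweep(X[, nz, drop = FALSE], 2L, rng[nz], "/")
  Xn[, !nz] <- 0
  # Manhattan distances on the normalised features
  Dist <- as.matrix(stats::dist(Xn, method = "manhattan"))

  priors <- as.numeric(counts) / n
  names(priors) <- names(counts)
  classIdx <- split(seq_len(n), y)

  refs <- if (is.na(config@mSamples) || config@mSamples >= n) seq_len(n)
  else with_seed(stream_seed(config@seed, "relieff"),
                 sort(sample.int(n, config@mSamples)))
  m <- length(refs)

  W <- numeric(p)
  for (i in refs) {
    ci <- as.character(y[i])
    hits <- nearest_k(Dist[i, ], setdiff(classIdx[[ci]], i), k)
    hitSum <- colSums(abs(Xn[hits, , drop = FALSE] -
                          rep(Xn[i, ], each = length(hits))))
    missSum <- numeric(p)
    for (cm in setdiff(names(classIdx), ci)) {
      mj <- nearest_k(Dist[i, ], classIdx[[cm]], min(k, length(classIdx[[cm]])))
      scale <- priors[[cm]] / (1 - priors[[ci]])
      missSum <- missSum + scale *
        colSums(abs(Xn[mj, , drop = FALSE] -
                    rep(Xn[i, ], each = length(mj))))
    }
    W <- W - hitSum / (m * k) + missSum / (m * k)
  }
  names(W) <- colnames(X)
  new("ReliefFWeights", W = W, priors = priors, kUsed = as.integer(k))
}

#' Threshold ReliefF weights into a keep-mask
#'
#' Keeps features whose importance weight is at least `threshold`.
#'
#' @param W numeric weights or a [ReliefFWeights-class] object.
#' @param threshold importance threshold (default 0.01).
#' @return logical keep-mask; an empty selection triggers a warning.
#' @examples
#' selectByImportance(c(0.009, 0.01, 0.5), 0.01)
#' @export
selectByImportance <- function(W, threshold = 0.01) {
  if (is(W, "ReliefFWeights")) W <- featureWeights(W)
  mask <- as.numeric(W) >= threshold
  if (!any(mask))
    warning("no importance weight reaches the threshold; empty selection")
  mask
}
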
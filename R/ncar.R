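# NCAR multilevel feature selection: NCA weighting thresholded at thr1
# (level 1), then ReliefF importance weighting recomputed on the
# survivors and thresholded at thr2 (level 2).  The literal single-vector
# ratio-reduction variant is provided separately as ratioReduce().

#' Two-level NCAR feature selection
#'
#' Level 1 fits NCA feature weights ([fitNCA()]) and keeps features with
#' weight `>= thr1`; level 2 recomputes ReliefF importance weights
#' ([relieffWeights()]) on the surviving columns and keeps those with
#' importance `>= thr2`.  The returned mask maps the level-2 survivors
#' back to the original column indices.  Raising either threshold can
#' only shrink the selection (given the same fitted weights).
#'
#' @param X numeric matrix (n x p).
#' @param y class labels.
#' @param ncaCfg an [ncaConfig()] for level 1.
#' @param relieffCfg a [relieffConfig()] for level 2.
#' @param thr1 NCA weight threshold (default 0.0005).
#' @param thr2 ReliefF importance threshold (default 0.01).
#' @param n1,n2 optional per-level survivor counts.  Absolute weight
#'   thresholds are calibrated to a particular weight scale; fixing the
#'   number of survivors instead (e.g. the reference operating point of
#'   58 after level 1 and 30 after level 2) gives a scale-free cutoff.
#'   When given, the corresponding threshold is replaced by the weight of
#'   the `n`-th best feature at that level.
#' @return a [SelectionResult-class] object.
#' @examples
#' tab <- generateFeatureTable(synthTableSpec(nSamples = 80, nFeatures = 10,
#'   nInformative = 3, effectSize = 4, seed = 11))
#' res <- ncarSelect(tab$X, tab$y, ncaConfig(maxIters = 30))
#' selectedFeatures(res)
#' @export
ncarSelect <- function(X, y, ncaCfg = ncaConfig(),
                       relieffCfg = relieffConfig(),
                       thr1 = 5e-4, thr2 = 0.01, n1 = NULL, n2 = NULL) {
  X <- check_feature_matrix(X, y)
  y <- as_label_factor(y, nrow(X))
  p <- ncol(X)

  l1 <- fitNCA(X, y, ncaCfg)
  if (!is.null(n1))
    thr1 <- sort(featureWeights(l1), decreasing = TRUE)[min(n1, p)]
  mask1 <- suppressWarnings(selectByWeight(l1, thr1))
  if (!any(mask1))
    stop("level-1 NCA threshold removed every feature; lower thr1 ",
         sprintf("(max weight was %.4g)", max(featureWeights(l1))))
  survivors <- which(mask1)

  l2 <- relieffWeights(X[, survivors, drop = FALSE], y, relieffCfg)
  if (!is.null(n2))
    thr2 <- sort(featureWeights(l2),
                 decreasing = TRUE)[min(n2, length(survivors))]
  mask2 <- suppressWarnings(selectByImportance(l2, thr2))

  keep <- logical(p)
  keep[survivors[mask2]] <- TRUE
  if (!any(keep))
    warning("level-2 ReliefF threshold removed every surviving feature")
  new("SelectionResult", keepMask = keep, level1Weights = l1,
      level1Survivors = as.integer(survivors), level2Weights = l2,
      thresholds = c(thr1 = unname(thr1), thr2 = unname(thr2)),
      nSelected = as.integer(sum(keep)))
}

#' Ratio-based reduction of a single feature vector
#'
#' Removes element `i` of `fea` when both `std/fea[i] > thr` and
#' `avg/fea[i] > thr`, where `avg` and `std` (population standard
#' deviation) are computed once from the input vector and not updated
#' during the loop.  Elements equal to 0 make both ratios infinite and
#' are removed for any finite threshold.
#'
#' @param fea non-empty numeric vector.
#' @param thr threshold for both ratios.
#' @return the reduced numeric vector.
#' @examples
#' ratioReduce(c(1, 10), thr = 1)  # keeps only 10
#' @export
ratioReduce <- function(fea, thr) {
  fea <- as.numeric(fea)
  if (!length(fea)) stop("fea must be non-empty")
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr))
    stop("'thr' must be a numeric scalar (possibly infinite)")
  avg <- mean(fea)
  std <- sqrt(mean((fea - avg)^2))            # population SD
  d1 <- ifelse(fea == 0, Inf, std / fea)
  d2 <- ifelse(fea == 0, Inf, avg / fea)
  fea[!(d1 > thr & d2 > thr)]
}
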
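# Classifier evaluation harness: one-vs-rest per-class metrics from a
# confusion matrix, macro averages, and seeded stratified k-fold
# cross-validation for the DT / LD / NB / SVM / KNN families, with
# one-vs-rest ROC AUCs computed from per-class decision scores.

#' One-vs-rest F-score
#'
#' `F = 2 * sens * prec / (sens + prec)`, `NaN` when the denominator is 0.
#'
#' @param sensitivity,precision numeric vectors in `[0, 1]`.
#' @return numeric vector of F-scores.
#' @examples
#' fScore(0.8020, 0.9916)
#' @export
fScore <- function(sensitivity, precision) {
  den <- sensitivity + precision
  ifelse(den > 0, 2 * sensitivity * precision / den, NaN)
}

#' Per-class metrics from a confusion matrix
#'
#' Treats each class one-vs-rest (truth in rows, prediction in columns)
#' and reports sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)` and the F-score.  Undefined ratios (zero
#' denominators) are reported as `NaN` with a warning.
#'
#' @param confusion square numeric matrix; `dimnames` supply class names.
#' @return a [MetricsReport-class] (without fold assignments or AUCs).
#' @examples
#' perClassMetrics(matrix(c(8, 1, 2, 9), 2, 2))
#' @export
perClassMetrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  C <- nrow(confusion)
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- paste0("C", seq_len(C))
  tot <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- tot - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, NaN)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f <- fScore(sens, prec)
  if (anyNA(c(sens, spec, prec, f)))
    warning("some per-class ratios are undefined (zero denominator); ",
            "reported as NaN")
  pc <- data.frame(class = cls, sensitivity = sens, specificity = spec,
                   precision = prec, fScore = f, row.names = NULL)
  macro <- c(sensitivity = mean(sens), specificity = mean(spec),
             precision = mean(prec), fScore = mean(f))
  new("MetricsReport", confusion = confusion, perClass = pc, macro = macro,
      accuracy = sum(tp) / tot, aucOvr = numeric(),
      foldAssignments = integer())
}

#' Macro (unweighted) average over classes
#'
#' @param perClassValues numeric vector of a per-class metric, or the
#'   `perClass` data frame of a [MetricsReport-class] (then every metric
#'   column is averaged).
#' @return numeric scalar or named vector of class means.
#' @examples
#' macroAverage(c(0.8, 0.9, 1.0))
#' @export
macroAverage <- function(perClassValues) {
  if (is.data.frame(perClassValues)) {
    num <- vapply(perClassValues, is.numeric, logical(1))
    colMeans(perClassValues[num])
  } else mean(as.numeric(perClassValues))
}

# Seeded stratified fold assignment: within each class, shuffled samples
# are dealt round-robin over folds, so fold sizes differ by at most one
# per class.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(stream_seed(seed, "folds"), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Fit one classifier on (X, y) and return predicted labels plus a
# per-class numeric score matrix for the test rows.
fit_predict <- function(spec, Xtr, ytr, Xte) {
  lev <- levels(ytr)
  hp <- spec@hyperparameters
  tr <- data.frame(Xtr, check.names = FALSE); tr$.y <- ytr
  te <- data.frame(Xte, check.names = FALSE)
  switch(spec@kind,
    DT = {
      ctrl <- rpart::rpart.control(xval = 0)
      fit <- do.call(rpart::rpart,
                     c(list(.y ~ ., data = tr, method = "class",
                            control = ctrl), hp))
      sc <- predict(fit, te, type = "prob")
      list(pred = factor(lev[max.col(sc[, lev, drop = FALSE], ties.method = "first")], levels = lev),
           scores = sc[, lev, drop = FALSE])
    },
    LD = {
      fit <- do.call(MASS::lda, c(list(x = Xtr, grouping = ytr), hp))
      pr <- predict(fit, Xte)
      sc <- pr$posterior[, lev, drop = FALSE]
      list(pred = factor(as.character(pr$class), levels = lev), scores = sc)
    },
    NB = {
      fit <- do.call(e1071::naiveBayes,
                     c(list(.y ~ ., data = tr), hp))
      sc <- predict(fit, Xte, type = "raw")[, lev, drop = FALSE]
      list(pred = factor(lev[max.col(sc, ties.method = "first")], levels = lev), scores = sc)
    },
    SVM = {
      fit <- do.call(e1071::svm,
                     c(list(x = Xtr, y = ytr, kernel = "radial",
                            decision.values = TRUE), hp))
      pr <- predict(fit, Xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sc <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
      # aggregate pairwise margins: +margin for the first class of the
      # pair, -margin for the second
      for (nm in colnames(dv)) {
        pair <- strsplit(nm, "/", fixed = TRUE)[[1L]]
        sc[, pair[1L]] <- sc[, pair[1L]] + dv[, nm]
        sc[, pair[2L]] <- sc[, pair[2L]] - dv[, nm]
      }
      list(pred = factor(as.character(pr), levels = lev), scores = sc)
    },
    KNN = {
      k <- if (!is.null(hp$k)) hp$k else 1L
      sc <- knn_scores(Xtr, ytr, Xte, k)
      list(pred = factor(lev[max.col(sc, ties.method = "first")], levels = lev), scores = sc)
    },
    stop("unknown classifier kind: ", spec@kind))
}

# k-nearest-neighbour vote fractions (Euclidean distance, distance then
# index tie-break); returns an nTest x nLevels score matrix.
knn_scores <- function(Xtr, ytr, Xte, k) {
  lev <- levels(ytr)
  k <- min(k, nrow(Xtr))
  sc <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
  tr2 <- rowSums(Xtr^2)
  for (i in seq_len(nrow(Xte))) {
    d <- tr2 - 2 * drop(Xtr %*% Xte[i, ])
    nn <- order(d, seq_along(d))[seq_len(k)]
    tab <- table(factor(ytr[nn], levels = lev))
    sc[i, ] <- as.numeric(tab) / k
  }
  sc
}

ovr_aucs <- function(y, scores) {
  lev <- levels(y)
  aucs <- vapply(lev, function(cl) {
    resp <- as.integer(y == cl)
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, scores[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  c(aucs, macro = mean(aucs, na.rm = TRUE))
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Assigns samples to `k` stratified folds (seeded, reproducible), fits
#' the classifier on each training split with features z-scored using
#' training-fold statistics only, pools the held-out predictions into a
#' single confusion matrix, and computes one-vs-rest AUCs from the
#' pooled decision scores.
#'
#' @param X numeric feature matrix (n x p) or a [DeepFeatureSet-class].
#' @param y class labels; classes smaller than `k` reduce `k` with a
#'   warning.
#' @param spec a [classifierSpec()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return a [MetricsReport-class] with pooled confusion, per-class
#'   metrics, macro averages, accuracy, AUCs and the fold assignment.
#' @examples
#' tab <- generateFeatureTable(synthTableSpec(nSamples = 60, nFeatures = 6,
#'   nInformative = 2, effectSize = 6, seed = 5))
#' rep <- stratifiedCV(tab$X, tab$y, classifierSpec("LD"), k = 3)
#' accuracy(rep)
#' @export
stratifiedCV <- function(X, y, spec = classifierSpec("SVM"), k = 10L,
                         seed = 1L) {
  if (is(X, "DeepFeatureSet")) X <- featureMatrix(X)
  X <- check_feature_matrix(X, y)
  y <- as_label_factor(y, nrow(X))
  validObject(spec)
  minClass <- min(table(y))
  if (minClass < k) {
    k <- max(2L, as.integer(minClass))
    warning(sprintf("smallest class has %d members; k reduced to %d",
                    minClass, k))
  }
  folds <- stratified_folds(y, k, seed)
  lev <- levels(y)
  pred <- factor(rep(lev[1L], length(y)), levels = lev)
  scores <- matrix(0, length(y), length(lev), dimnames = list(NULL, lev))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], mu, sdv)
    Xte <- scale(X[te, , drop = FALSE], mu, sdv)
    r <- with_seed(stream_seed(spec@seed, "misc"),
                   fit_predict(spec, Xtr, droplevels(y[tr]), Xte))
    pred[te] <- factor(as.character(r$pred), levels = lev)
    scores[te, colnames(r$scores)] <- r$scores
  }
  conf <- table(truth = y, prediction = pred)
  rep <- perClassMetrics(unclass(as.matrix(conf)))
  rep@aucOvr <- ovr_aucs(y, scores)
  rep@foldAssignments <- as.integer(folds)
  rep
}
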
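# End-to-end pipeline: deep-feature extraction -> NCAR selection ->
# cross-validated classification.
#
# Two evaluation modes are provided.  "paper" reproduces the reference
# protocol: the extractor is trained on ALL images, features are
# extracted and selected once, and only the final classifier is
# cross-validated.  That protocol leaks information from the evaluation
# folds into the extractor and the selector, so an "honest" mode is also
# provided in which extraction and selection are re-done inside each
# training fold.  Paper mode is the default for fidelity; honest-mode
# accuracies are expected to be no higher.

#' Run the full extract -> select -> classify pipeline
#'
#' For image input, trains the CNN(+LSTM) extractor, extracts deep
#' features from the first fully connected layer, applies NCAR selection
#' and cross-validates the classifier.  A plain feature matrix skips the
#' extraction stage.
#'
#' @param images array `H x W x 3 x N`, or `NULL` when `features` given.
#' @param labels class labels of length N.
#' @param features optional numeric matrix (n x p) or
#'   [DeepFeatureSet-class]; used directly instead of images.
#' @param modelCfg a [modelConfig()] (image input only).
#' @param trainCfg a [trainConfig()] (image input only).
#' @param ncaCfg,relieffCfg,thr1,thr2,n1,n2 NCAR settings, as
#'   [ncarSelect()].
#' @param classifier a [classifierSpec()] (default SVM).
#' @param cvFolds number of CV folds (default 10).
#' @param mode `"paper"` (train extractor and select on all data, CV the
#'   classifier only) or `"honest"` (nest extraction and selection in
#'   each fold).
#' @param seed master seed for model initialisation and fold assignment.
#' @param select apply NCAR selection (set `FALSE` to evaluate on all
#'   features).
#' @return a list with `metrics` (a [MetricsReport-class]), `selection`
#'   (a [SelectionResult-class] or `NULL`), `features` (the
#'   [DeepFeatureSet-class] or input matrix), `model` (the trained
#'   [RCNNLSTM-class] or `NULL`) and `history`.
#' @export
runPipeline <- function(images = NULL, labels, features = NULL,
                        modelCfg = modelConfig(), trainCfg = trainConfig(),
                        ncaCfg = ncaConfig(), relieffCfg = relieffConfig(),
                        thr1 = 5e-4, thr2 = 0.01, n1 = NULL, n2 = NULL,
                        classifier = classifierSpec("SVM"), cvFolds = 10L,
                        mode = c("paper", "honest"), seed = 1L,
                        select = TRUE) {
  mode <- match.arg(mode)
  y <- as_label_factor(labels)
  model <- NULL

  if (is.null(features)) {
    if (is.null(images)) stop("provide either images or features")
    if (mode == "paper") {
      model <- buildModel(modelCfg, seed = seed)
      model <- trainModel(model, images, y, trainCfg)
      features <- extractDeepFeatures(model, images)
    }
  } else if (is(features, "DeepFeatureSet")) {
    features <- featureMatrix(features)
  }

  if (mode == "paper") {
    X <- if (is(features, "DeepFeatureSet")) featureMatrix(features)
         else as.matrix(features)
    sel <- NULL
    if (select) {
      sel <- ncarSelect(X, y, ncaCfg, relieffCfg, thr1, thr2, n1, n2)
      if (nSelected(sel) == 0L)
        stop("NCAR selection kept no features; lower the thresholds")
      X <- X[, keepMask(sel), drop = FALSE]
    }
    metrics <- stratifiedCV(X, y, classifier, k = cvFolds, seed = seed)
    return(list(metrics = metrics, selection = sel, features = features,
                model = model,
                history = if (is.null(model)) NULL else model@history))
  }

  # honest mode: everything inside the folds
  n <- length(y)
  minClass <- min(table(y))
  k <- cvFolds
  if (minClass < k) {
    k <- max(2L, as.integer(minClass))
    warning(sprintf("smallest class has %d members; k reduced to %d",
                    minClass, k))
  }
  folds <- stratified_folds(y, k, seed)
  lev <- levels(y)
  pred <- factor(rep(lev[1L], n), levels = lev)
  scores <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  for (f in seq_len(k)) {
    trIdx <- which(folds != f); teIdx <- which(folds == f)
    if (is.null(features)) {
      mdl <- buildModel(modelCfg, seed = seed + f)
      mdl <- trainModel(mdl, images[, , , trIdx, drop = FALSE], y[trIdx],
                        trainCfg)
      Xtr <- featureMatrix(extractDeepFeatures(
        mdl, images[, , , trIdx, drop = FALSE]))
      Xte <- featureMatrix(extractDeepFeatures(
        mdl, images[, , , teIdx, drop = FALSE]))
    } else {
      Xall <- as.matrix(features)
      Xtr <- Xall[trIdx, , drop = FALSE]
      Xte <- Xall[teIdx, , drop = FALSE]
    }
    if (select) {
      sel <- ncarSelect(Xtr, y[trIdx], ncaCfg, relieffCfg, thr1, thr2, n1, n2)
      if (nSelected(sel) > 0L) {
        Xtr <- Xtr[, keepMask(sel), drop = FALSE]
        Xte <- Xte[, keepMask(sel), drop = FALSE]
      }
    }
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    r <- with_seed(stream_seed(classifier@seed, "misc"),
                   fit_predict(classifier, scale(Xtr, mu, sdv),
                               droplevels(y[trIdx]), scale(Xte, mu, sdv)))
    pred[teIdx] <- factor(as.character(r$pred), levels = lev)
    scores[teIdx, colnames(r$scores)] <- r$scores
  }
  conf <- unclass(as.matrix(table(truth = y, prediction = pred)))
  metrics <- perClassMetrics(conf)
  metrics@aucOvr <- ovr_aucs(y, scores)
  metrics@foldAssignments <- as.integer(folds)
  list(metrics = metrics, selection = NULL, features = features,
       model = NULL, history = NULL)
}
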
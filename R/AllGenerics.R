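# Generics and accessor/show methods for the package's S4 classes.

#' Extract the numeric feature matrix
#' @param x an object holding features.
#' @return numeric matrix, samples in rows.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Sample identifiers
#' @param x an object holding per-sample data.
#' @return character vector.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Per-feature weights of a fitted selector
#' @param x an [NCAWeights-class] or [ReliefFWeights-class] object.
#' @return numeric vector, one weight per feature.
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))

#' Objective values of accepted ascent steps
#' @param x an [NCAWeights-class] object.
#' @return numeric vector (non-decreasing).
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' Logical keep-mask over the original features
#' @param x a [SelectionResult-class] object.
#' @return logical vector.
#' @export
setGeneric("keepMask", function(x) standardGeneric("keepMask"))

#' Number of selected features
#' @param x a [SelectionResult-class] object.
#' @return integer.
#' @export
setGeneric("nSelected", function(x) standardGeneric("nSelected"))

#' Indices of the selected features
#' @param x a [SelectionResult-class] object.
#' @return integer vector of original column indices.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' Pooled confusion matrix of a metrics report
#' @param x a [MetricsReport-class] object.
#' @return integer matrix, truth in rows.
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' Per-class one-vs-rest metrics
#' @param x a [MetricsReport-class] object.
#' @return data frame with sensitivity, specificity, precision, fScore.
#' @export
setGeneric("perClass", function(x) standardGeneric("perClass"))

#' Overall accuracy
#' @param x a [MetricsReport-class] object.
#' @return numeric scalar in `[0, 1]`.
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' Macro-averaged metrics
#' @param x a [MetricsReport-class] object.
#' @return named numeric vector.
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' One-vs-rest AUCs
#' @param x a [MetricsReport-class] object.
#' @return named numeric vector with one AUC per class plus `"macro"`.
#' @export
setGeneric("aucOvr", function(x) standardGeneric("aucOvr"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "DeepFeatureSet", function(x) x@matrix)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "DeepFeatureSet", function(x) x@sampleIds)

#' @rdname featureWeights
#' @export
setMethod("featureWeights", "NCAWeights", function(x) x@w)

#' @rdname featureWeights
#' @export
setMethod("featureWeights", "ReliefFWeights", function(x) x@W)

#' @rdname objectiveTrace
#' @export
setMethod("objectiveTrace", "NCAWeights", function(x) x@objectiveTrace)

#' @rdname keepMask
#' @export
setMethod("keepMask", "SelectionResult", function(x) x@keepMask)

#' @rdname nSelected
#' @export
setMethod("nSelected", "SelectionResult", function(x) x@nSelected)

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) which(x@keepMask))

#' @rdname confusionMatrix
#' @export
setMethod("confusionMatrix", "MetricsReport", function(x) x@confusion)

#' @rdname perClass
#' @export
setMethod("perClass", "MetricsReport", function(x) x@perClass)

#' @rdname accuracy
#' @export
setMethod("accuracy", "MetricsReport", function(x) x@accuracy)

#' @rdname macroMetrics
#' @export
setMethod("macroMetrics", "MetricsReport", function(x) x@macro)

#' @rdname aucOvr
#' @export
setMethod("aucOvr", "MetricsReport", function(x) x@aucOvr)

setMethod("show", "SynthTableSpec", function(object) {
  cat(sprintf(
    "SynthTableSpec: %d samples x %d features (%d informative), %d classes\n",
    object@nSamples, object@nFeatures, object@nInformative, object@nClasses))
  cat(sprintf("  effectSize %.3g (noise sd %.3g), seed %d\n",
              object@effectSize, object@noiseSd, object@seed))
})

setMethod("show", "SynthImageSpec", function(object) {
  cat(sprintf("SynthImageSpec: %d x %d RGB phantoms, %d per class, seed %d\n",
              object@imageSize, object@imageSize, object@nPerClass,
              object@seed))
  cat("  classes:", paste(object@classNames, collapse = ", "), "\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig (%s): input %dx%dx3, stem %d filters\n",
              object@variant, object@inputSize, object@inputSize,
              object@stemFilters))
  cat(sprintf("  %d blocks [%s], kernel %d\n", object@nResidualBlocks,
              paste(object@blockFilters, collapse = ","), object@kernelSize))
  seqpart <- if (object@variant %in% c("cnn_lstm", "rcnn_lstm"))
    sprintf("LSTM(%d)", object@lstmUnits) else "flatten"
  cat(sprintf("  %s -> FC(%d) -> dropout %.2f -> FC(%d) -> softmax\n",
              seqpart, object@fc1Width, object@dropoutRate, object@nClasses))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: batch %d, lr %.4g, %d epochs, momentum %.2f, seed %d\n",
    object@batchSize, object@learningRate, object@maxEpochs, object@momentum,
    object@seed))
})

setMethod("show", "DeepFeatureSet", function(object) {
  cat(sprintf("DeepFeatureSet: %d samples x %d deep features\n",
              nrow(object@matrix), ncol(object@matrix)))
  cat("  source:", object@source, "\n")
})

setMethod("show", "NCAWeights", function(object) {
  cat(sprintf("NCAWeights: %d features, lambda %.4g, %s after %d steps\n",
              length(object@w), object@lambdaReg,
              if (object@converged) "converged" else "not converged",
              length(object@objectiveTrace) - 1L))
  cat(sprintf("  final objective %.6g, weight range [%.4g, %.4g]\n",
              utils::tail(object@objectiveTrace, 1L),
              min(object@w), max(object@w)))
})

setMethod("show", "ReliefFWeights", function(object) {
  cat(sprintf("ReliefFWeights: %d features, k = %d\n",
              length(object@W), object@kUsed))
  cat(sprintf("  weight range [%.4g, %.4g]\n", min(object@W), max(object@W)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: %d / %d features kept (thr1 %.4g -> %d, thr2 %.4g)\n",
    object@nSelected, length(object@keepMask), object@thresholds[1L],
    length(object@level1Survivors), object@thresholds[2L]))
})

setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf("ClassifierSpec: %s", object@kind))
  if (length(object@hyperparameters))
    cat(" (", paste(names(object@hyperparameters),
                    unlist(object@hyperparameters),
                    sep = "=", collapse = ", "), ")", sep = "")
  cat("\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: %d classes, %d samples, accuracy %.4f\n",
              nrow(object@confusion), sum(object@confusion), object@accuracy))
  cat(sprintf("  macro sens %.4f spec %.4f prec %.4f F %.4f",
              object@macro[["sensitivity"]], object@macro[["specificity"]],
              object@macro[["precision"]], object@macro[["fScore"]]))
  if ("macro" %in% names(object@aucOvr))
    cat(sprintf(", macro AUC %.4f", object@aucOvr[["macro"]]))
  cat("\n")
})
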
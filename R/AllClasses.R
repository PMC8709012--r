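#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

# ---------------------------------------------------------------------------
# Synthetic-data specifications
# ---------------------------------------------------------------------------

#' Specification of a synthetic labelled feature table
#'
#' Describes a multi-class Gaussian feature table with a known informative
#' subset: the class means of the informative columns sit on a regular
#' simplex whose edge length is `effectSize * noiseSd`, while the remaining
#' columns are class-independent noise.
#'
#' @slot nSamples number of rows.
#' @slot nFeatures number of feature columns.
#' @slot nInformative number of class-informative columns (first columns).
#' @slot nClasses number of classes (labels `C1..Ck`).
#' @slot effectSize class-mean separation in units of `noiseSd`.
#' @slot noiseSd within-class standard deviation of every feature.
#' @slot seed RNG seed for the table stream.
#' @name SynthTableSpec-class
#' @aliases SynthTableSpec
#' @exportClass SynthTableSpec
setClass("SynthTableSpec",
  representation(nSamples = "integer", nFeatures = "integer",
                 nInformative = "integer", nClasses = "integer",
                 effectSize = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be positive")
    if (object@nFeatures < 1L) msg <- c(msg, "nFeatures must be positive")
    if (object@nInformative < 0L) msg <- c(msg, "nInformative must be >= 0")
    if (object@nInformative > object@nFeatures)
      msg <- c(msg, "nInformative must not exceed nFeatures")
    if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
    if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Create a synthetic feature-table specification
#'
#' @param nSamples,nFeatures,nInformative,nClasses table dimensions; see
#'   [SynthTableSpec-class].
#' @param effectSize class-mean separation in noise-SD units.
#' @param noiseSd within-class standard deviation.
#' @param seed integer RNG seed.
#' @return a [SynthTableSpec-class] object.
#' @examples
#' synthTableSpec(nSamples = 100, nFeatures = 10, nInformative = 3)
#' @export
synthTableSpec <- function(nSamples = 200L, nFeatures = 20L,
                           nInformative = 4L, nClasses = 2L,
                           effectSize = 3, noiseSd = 1, seed = 1L) {
  new("SynthTableSpec",
      nSamples = as.integer(nSamples), nFeatures = as.integer(nFeatures),
      nInformative = as.integer(nInformative), nClasses = as.integer(nClasses),
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Names of the eight phantom classes
#'
#' The class vocabulary mirrors the eight ophthalmic categories commonly
#' used for fundus-image classification.
#' @return character vector of valid phantom class names.
#' @export
phantomClassNames <- function() {
  c("AMD", "Cataract", "Diabetes", "Glaucoma",
    "Hypertension", "Normal", "Other", "PM")
}

#' Specification of a fundus-like phantom image set
#'
#' @slot nPerClass images per class.
#' @slot classNames subset of [phantomClassNames()].
#' @slot imageSize side length in pixels (square RGB images), `>= 32`.
#' @slot seed RNG seed for the image stream.
#' @name SynthImageSpec-class
#' @aliases SynthImageSpec
#' @exportClass SynthImageSpec
setClass("SynthImageSpec",
  representation(nPerClass = "integer", classNames = "character",
                 imageSize = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nPerClass < 1L) msg <- c(msg, "nPerClass must be positive")
    bad <- setdiff(object@classNames, phantomClassNames())
    if (length(bad))
      msg <- c(msg, sprintf("unknown class name(s) %s; valid names are: %s",
                            paste(sQuote(bad), collapse = ", "),
                            paste(phantomClassNames(), collapse = ", ")))
    if (!length(object@classNames)) msg <- c(msg, "classNames must be non-empty")
    if (anyDuplicated(object@classNames)) msg <- c(msg, "duplicate class names")
    if (object@imageSize < 32L) msg <- c(msg, "imageSize must be >= 32")
    if (length(msg)) msg else TRUE
  })

#' Create a phantom image-set specification
#'
#' @param nPerClass images per class.
#' @param classNames subset of [phantomClassNames()].
#' @param imageSize square side length in pixels (default 125).
#' @param seed integer RNG seed.
#' @return a [SynthImageSpec-class] object.
#' @examples
#' synthImageSpec(nPerClass = 2, classNames = c("Normal", "Glaucoma"))
#' @export
synthImageSpec <- function(nPerClass = 10L, classNames = phantomClassNames(),
                           imageSize = 125L, seed = 1L) {
  new("SynthImageSpec", nPerClass = as.integer(nPerClass),
      classNames = as.character(classNames),
      imageSize = as.integer(imageSize), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Model configuration
# ---------------------------------------------------------------------------

#' Architecture configuration for the residual CNN+LSTM extractor
#'
#' Defaults follow the reference architecture: a convolutional stem, six
#' residual blocks (each two conv units with batch normalisation and a
#' ReLU, plus a skip connection), row-wise unfolding into a sequence, an
#' LSTM with 100 units, and a 350-wide first fully connected layer whose
#' activations are the deep features.
#'
#' @slot nResidualBlocks number of (residual) blocks.
#' @slot stemFilters filters in the stem convolution.
#' @slot blockFilters integer vector, one filter count per block.
#' @slot kernelSize convolution kernel side (odd).
#' @slot lstmUnits LSTM hidden size.
#' @slot fc1Width width of the first fully connected (deep-feature) layer.
#' @slot nClasses number of output classes.
#' @slot dropoutRate dropout probability before the class head.
#' @slot inputSize input image side length.
#' @slot variant one of `"cnn"`, `"cnn_lstm"`, `"rcnn"`, `"rcnn_lstm"`;
#'   `cnn*` variants drop the skip connections, `*_lstm` variants use the
#'   LSTM stage (otherwise the final map is flattened).
#' @name ModelConfig-class
#' @aliases ModelConfig
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(nResidualBlocks = "integer", stemFilters = "integer",
                 blockFilters = "integer", kernelSize = "integer",
                 lstmUnits = "integer", fc1Width = "integer",
                 nClasses = "integer", dropoutRate = "numeric",
                 inputSize = "integer", variant = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@variant %in% c("cnn", "cnn_lstm", "rcnn", "rcnn_lstm"))
      msg <- c(msg, "variant must be one of cnn, cnn_lstm, rcnn, rcnn_lstm")
    if (object@fc1Width < 1L) msg <- c(msg, "fc1Width must be positive")
    if (object@nResidualBlocks < 1L) msg <- c(msg, "need at least one block")
    if (length(object@blockFilters) != object@nResidualBlocks)
      msg <- c(msg, "blockFilters must have one entry per block")
    if (object@kernelSize %% 2L != 1L) msg <- c(msg, "kernelSize must be odd")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
    if (length(msg)) msg else TRUE
  })

#' Create a model configuration
#'
#' @param nResidualBlocks,stemFilters,blockFilters,kernelSize,lstmUnits
#'   architecture constants; see [ModelConfig-class].
#' @param fc1Width width of the deep-feature layer (default 350).
#' @param nClasses number of classes.
#' @param dropoutRate dropout before the class head (default 0.2).
#' @param inputSize input image side (default 125).
#' @param variant architecture variant (default `"rcnn_lstm"`).
#' @return a [ModelConfig-class] object.
#' @examples
#' modelConfig(nClasses = 8)
#' @export
modelConfig <- function(nResidualBlocks = 6L, stemFilters = 8L,
                        blockFilters = c(16L, 16L, 32L, 32L, 64L, 64L),
                        kernelSize = 3L, lstmUnits = 100L, fc1Width = 350L,
                        nClasses = 2L, dropoutRate = 0.2, inputSize = 125L,
                        variant = c("rcnn_lstm", "rcnn", "cnn_lstm", "cnn")) {
  variant <- match.arg(variant)
  new("ModelConfig", nResidualBlocks = as.integer(nResidualBlocks),
      stemFilters = as.integer(stemFilters),
      blockFilters = as.integer(blockFilters),
      kernelSize = as.integer(kernelSize), lstmUnits = as.integer(lstmUnits),
      fc1Width = as.integer(fc1Width), nClasses = as.integer(nClasses),
      dropoutRate = as.numeric(dropoutRate), inputSize = as.integer(inputSize),
      variant = variant)
}

#' Optimisation settings for network training
#'
#' Defaults follow the reference protocol: mini-batch size 128, initial
#' learning rate 0.001, at most 150 epochs, stochastic gradient descent
#' with momentum (SGDM) and a cross-entropy loss.
#'
#' @slot batchSize mini-batch size.
#' @slot learningRate SGD learning rate.
#' @slot maxEpochs number of passes over the data.
#' @slot momentum SGDM momentum coefficient.
#' @slot seed RNG seed governing shuffling and dropout.
#' @name TrainConfig-class
#' @aliases TrainConfig
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batchSize = "integer", learningRate = "numeric",
                 maxEpochs = "integer", momentum = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@maxEpochs < 0L) msg <- c(msg, "maxEpochs must be >= 0")
    if (object@momentum < 0 || object@momentum >= 1)
      msg <- c(msg, "momentum must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Create a training configuration
#'
#' @param batchSize mini-batch size (default 128).
#' @param learningRate initial learning rate (default 0.001).
#' @param maxEpochs maximum epochs (default 150).
#' @param momentum SGDM momentum (default 0.9).
#' @param seed integer RNG seed.
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(batchSize = 128L, learningRate = 0.001,
                        maxEpochs = 150L, momentum = 0.9, seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate),
      maxEpochs = as.integer(maxEpochs), momentum = as.numeric(momentum),
      seed = as.integer(seed))
}

#' Deep-feature matrix extracted from a trained network
#'
#' @slot matrix numeric matrix, one row per image, `fc1Width` columns.
#' @slot sampleIds character identifiers aligned with rows.
#' @slot source description of the producing model and layer.
#' @name DeepFeatureSet-class
#' @aliases DeepFeatureSet
#' @exportClass DeepFeatureSet
setClass("DeepFeatureSet",
  representation(matrix = "matrix", sampleIds = "character",
                 source = "character"),
  validity = function(object) {
    if (nrow(object@matrix) != length(object@sampleIds))
      "sampleIds must align with matrix rows" else TRUE
  })

# ---------------------------------------------------------------------------
# Feature-selection results
# ---------------------------------------------------------------------------

#' NCA feature-selection configuration
#'
#' Settings for maximising the regularised neighbourhood component
#' analysis objective `F(w) = mean_i P_i - lambda * sum_r w_r^2` by
#' gradient ascent, where `P_i` is the stochastic-neighbour probability of
#' sample `i` being matched to a same-class sample.
#'
#' @slot lambdaReg regularisation parameter; `NULL` means `1/n` at fit time.
#' @slot kernelWidth kernel width `sigma` of the neighbour kernel.
#' @slot learningRate initial ascent step size.
#' @slot maxIters maximum accepted ascent steps.
#' @slot tol relative objective-change stopping tolerance.
#' @slot standardize z-score features before fitting.
#' @slot seed RNG seed (reserved for stochastic modes).
#' @name NCAConfig-class
#' @aliases NCAConfig
#' @exportClass NCAConfig
setClass("NCAConfig",
  representation(lambdaReg = "numericOrNULL", kernelWidth = "numeric",
                 learningRate = "numeric", maxIters = "integer",
                 tol = "numeric", standardize = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.null(object@lambdaReg) && object@lambdaReg < 0)
      msg <- c(msg, "lambdaReg must be >= 0")
    if (object@kernelWidth <= 0) msg <- c(msg, "kernelWidth must be > 0")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@maxIters < 1L) msg <- c(msg, "maxIters must be >= 1")
    if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Create an NCA configuration
#'
#' @param lambdaReg regularisation `lambda`; `NULL` (default) uses `1/n`.
#' @param kernelWidth kernel width `sigma` (default 1, appropriate for
#'   z-scored features).
#' @param learningRate initial step size for gradient ascent.
#' @param maxIters maximum accepted steps.
#' @param tol relative objective-change tolerance.
#' @param standardize z-score the features first (default `TRUE`).
#' @param seed integer RNG seed.
#' @return an [NCAConfig-class] object.
#' @export
ncaConfig <- function(lambdaReg = NULL, kernelWidth = 1, learningRate = 0.1,
                      maxIters = 100L, tol = 1e-5, standardize = TRUE,
                      seed = 1L) {
  new("NCAConfig",
      lambdaReg = if (is.null(lambdaReg)) NULL else as.numeric(lambdaReg),
      kernelWidth = as.numeric(kernelWidth),
      learningRate = as.numeric(learningRate), maxIters = as.integer(maxIters),
      tol = as.numeric(tol), standardize = as.logical(standardize),
      seed = as.integer(seed))
}

#' Fitted NCA feature weights
#'
#' @slot w per-feature weights.
#' @slot objectiveTrace objective values of accepted ascent steps
#'   (non-decreasing).
#' @slot converged whether the tolerance was reached before `maxIters`.
#' @slot lambdaReg the regularisation actually used.
#' @name NCAWeights-class
#' @aliases NCAWeights
#' @exportClass NCAWeights
setClass("NCAWeights",
  representation(w = "numeric", objectiveTrace = "numeric",
                 converged = "logical", lambdaReg = "numeric"),
  validity = function(object) {
    tr <- object@objectiveTrace
    if (length(tr) > 1L && any(diff(tr) < -1e-10))
      "objectiveTrace must be non-decreasing" else TRUE
  })

#' ReliefF configuration
#'
#' @slot kNeighbors number of nearest hits/misses per class (default 10;
#'   clipped with a warning when a class is too small).
#' @slot mSamples number of reference instances, or `NA` for all
#'   (deterministic).
#' @slot seed RNG seed, used only when `mSamples < n`.
#' @name ReliefFConfig-class
#' @aliases ReliefFConfig
#' @exportClass ReliefFConfig
setClass("ReliefFConfig",
  representation(kNeighbors = "integer", mSamples = "integer", seed = "integer"),
  validity = function(object) {
    if (object@kNeighbors < 1L) "kNeighbors must be >= 1" else TRUE
  })

#' Create a ReliefF configuration
#'
#' @param kNeighbors nearest neighbours per class (default 10).
#' @param mSamples instances to sample, or `"all"`/`NA` for every instance.
#' @param seed integer RNG seed (sampling mode only).
#' @return a [ReliefFConfig-class] object.
#' @export
relieffConfig <- function(kNeighbors = 10L, mSamples = "all", seed = 1L) {
  m <- if (identical(mSamples, "all") || is.na(mSamples[1L])) NA_integer_
       else as.integer(mSamples)
  new("ReliefFConfig", kNeighbors = as.integer(kNeighbors), mSamples = m,
      seed = as.integer(seed))
}

#' ReliefF importance weights
#'
#' @slot W per-feature importance weights in `[-1, 1]`.
#' @slot priors class prior estimates used for the miss terms.
#' @slot kUsed the neighbour count actually used after clipping.
#' @name ReliefFWeights-class
#' @aliases ReliefFWeights
#' @exportClass ReliefFWeights
setClass("ReliefFWeights",
  representation(W = "numeric", priors = "numeric", kUsed = "integer"))

#' Result of the two-level NCAR selection
#'
#' @slot keepMask logical vector over the original features.
#' @slot level1Weights fitted [NCAWeights-class] (level 1).
#' @slot level1Survivors original indices surviving the NCA threshold.
#' @slot level2Weights [ReliefFWeights-class] over the survivors (level 2).
#' @slot thresholds numeric `(thr1, thr2)`.
#' @slot nSelected number of features finally kept.
#' @name SelectionResult-class
#' @aliases SelectionResult
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(keepMask = "logical", level1Weights = "NCAWeights",
                 level1Survivors = "integer", level2Weights = "ReliefFWeights",
                 thresholds = "numeric", nSelected = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSelected != sum(object@keepMask))
      msg <- c(msg, "nSelected must equal the number of TRUE mask entries")
    if (!all(which(object@keepMask) %in% object@level1Survivors))
      msg <- c(msg, "kept features must be level-1 survivors")
    if (length(object@thresholds) != 2L)
      msg <- c(msg, "thresholds must have length 2")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# Evaluation
# ---------------------------------------------------------------------------

#' Classifier specification for the evaluation harness
#'
#' @slot kind one of `"DT"` (decision tree), `"LD"` (linear discriminant),
#'   `"NB"` (Gaussian naive Bayes), `"SVM"` (RBF support vector machine),
#'   `"KNN"` (k-nearest neighbours, default `k = 1`).
#' @slot hyperparameters named list passed to the underlying fitter.
#' @slot seed RNG seed for any stochastic fitter.
#' @name ClassifierSpec-class
#' @aliases ClassifierSpec
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
  representation(kind = "character", hyperparameters = "list", seed = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("DT", "LD", "NB", "SVM", "KNN"))
      "kind must be one of DT, LD, NB, SVM, KNN" else TRUE
  })

#' Create a classifier specification
#'
#' @param kind classifier family; see [ClassifierSpec-class].
#' @param hyperparameters named list of fitter arguments (e.g. `list(k = 5)`
#'   for KNN, `list(cost = 10)` for SVM).
#' @param seed integer RNG seed.
#' @return a [ClassifierSpec-class] object.
#' @examples
#' classifierSpec("SVM")
#' @export
classifierSpec <- function(kind = c("SVM", "DT", "LD", "NB", "KNN"),
                           hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  new("ClassifierSpec", kind = kind, hyperparameters = hyperparameters,
      seed = as.integer(seed))
}

#' Cross-validated classification metrics
#'
#' @slot confusion pooled confusion matrix (rows = truth, columns =
#'   prediction).
#' @slot perClass data frame of one-vs-rest sensitivity, specificity,
#'   precision and F-score per class.
#' @slot macro named numeric of unweighted class means of each metric.
#' @slot accuracy overall accuracy.
#' @slot aucOvr named numeric of one-vs-rest AUCs plus `"macro"`.
#' @slot foldAssignments integer fold id per sample (empty when the report
#'   did not come from cross-validation).
#' @name MetricsReport-class
#' @aliases MetricsReport
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 macro = "numeric", accuracy = "numeric", aucOvr = "numeric",
                 foldAssignments = "integer"),
  validity = function(object) {
    if (nrow(object@confusion) != ncol(object@confusion))
      "confusion matrix must be square" else TRUE
  })
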
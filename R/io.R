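# Plain-text interchange formats: feature tables (CSV with a trailing
# `label` column), weight and mask CSVs, metrics / selection / history
# JSON.  Every writer has a reader so round trips are exact.

#' Write a labelled feature table as CSV
#'
#' Columns `f1..fp` plus a final `label` column; comma separator, dot
#' decimal, header row, UTF-8.
#'
#' @param X numeric matrix.
#' @param y labels aligned with rows.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(X, y, path) {
  X <- check_feature_matrix(X, y)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$label <- as.character(y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled feature table from CSV
#'
#' @param path CSV written by [writeFeatureCSV()] (feature columns plus a
#'   `label` column).
#' @return list with `X` (numeric matrix) and `y` (factor).
#' @export
readFeatureCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df))
    stop("malformed feature CSV: no 'label' column in ", path)
  feat <- df[setdiff(names(df), "label")]
  if (!all(vapply(feat, is.numeric, logical(1))))
    stop("malformed feature CSV: non-numeric feature column in ", path)
  list(X = as.matrix(feat), y = factor(df$label))
}

#' Write per-feature weights as a two-column CSV
#'
#' @param w numeric weights, or an [NCAWeights-class] /
#'   [ReliefFWeights-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeWeightsCSV <- function(w, path) {
  if (is(w, "NCAWeights") || is(w, "ReliefFWeights")) w <- featureWeights(w)
  utils::write.csv(data.frame(feature_index = seq_along(w),
                              weight = as.numeric(w)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weights CSV
#' @param path file written by [writeWeightsCSV()].
#' @return numeric vector of weights in feature order.
#' @export
readWeightsCSV <- function(path) {
  df <- utils::read.csv(path)
  df$weight[order(df$feature_index)]
}

#' Write a 0/1 keep-mask CSV
#' @param mask logical vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMaskCSV <- function(mask, path) {
  utils::write.csv(data.frame(feature_index = seq_along(mask),
                              keep = as.integer(mask)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a keep-mask CSV
#' @param path file written by [writeMaskCSV()].
#' @return logical vector.
#' @export
readMaskCSV <- function(path) {
  df <- utils::read.csv(path)
  as.logical(df$keep[order(df$feature_index)])
}

#' Serialise a metrics report to JSON
#'
#' @param report a [MetricsReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMetricsJSON <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  obj <- list(confusion = unname(apply(report@confusion, 1L, as.integer,
                                       simplify = FALSE)),
              classes = rownames(report@confusion),
              perClass = report@perClass,
              macro = as.list(report@macro),
              accuracy = report@accuracy,
              aucOvr = as.list(report@aucOvr),
              foldAssignments = report@foldAssignments)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a metrics JSON back into a report
#' @param path file written by [writeMetricsJSON()].
#' @return a [MetricsReport-class].
#' @export
readMetricsJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- if (is.matrix(obj$confusion)) obj$confusion
          else do.call(rbind, lapply(obj$confusion, as.integer))
  storage.mode(conf) <- "integer"
  dimnames(conf) <- list(truth = obj$classes, prediction = obj$classes)
  new("MetricsReport", confusion = conf,
      perClass = as.data.frame(obj$perClass),
      macro = unlist(obj$macro), accuracy = obj$accuracy,
      aucOvr = unlist(obj$aucOvr),
      foldAssignments = as.integer(obj$foldAssignments %||% integer()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a selection result to JSON
#'
#' Stores the kept indices, the per-level survivors, thresholds and
#' counts (weights belong in the CSVs from [writeWeightsCSV()]).
#'
#' @param sel a [SelectionResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSelectionJSON <- function(sel, path) {
  stopifnot(is(sel, "SelectionResult"))
  obj <- list(nFeatures = length(sel@keepMask),
              selected = selectedFeatures(sel),
              level1Survivors = sel@level1Survivors,
              thresholds = as.list(sel@thresholds),
              nSelected = sel@nSelected)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a training history as JSON
#' @param history data frame with epoch/loss/accuracy columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHistoryJSON <- function(history, path) {
  jsonlite::write_json(history, path, dataframe = "columns", digits = NA)
  invisible(path)
}
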
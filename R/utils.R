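# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats predict rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

# Run expr under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive independent per-stream seeds from one master seed.  Streams are
# fixed per purpose so adding a new stream never perturbs existing ones.
# Kept strictly below 2^31 - 1.
stream_seed <- function(seed, stream) {
  offsets <- c(table = 101L, images = 202L, model = 303L, train = 404L,
               folds = 505L, nca = 606L, relieff = 707L, misc = 808L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483629)
}

stopifnot_scalar <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}

# z-score columns using the statistics of a reference matrix (defaults to
# the matrix itself).  Constant columns are centred but left unscaled.
zscore_columns <- function(x, ref = x) {
  mu <- colMeans(ref)
  sdv <- apply(ref, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  scale(x, center = mu, scale = sdv)[, , drop = FALSE]
}

as_label_factor <- function(y, n = NULL) {
  y <- as.factor(y)
  if (!is.null(n) && length(y) != n)
    stop("labels must align with the rows of the feature matrix", call. = FALSE)
  droplevels(y)
}

check_feature_matrix <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("feature matrix must be numeric", call. = FALSE)
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  if (!is.null(y) && nrow(X) != length(y))
    stop("feature matrix and labels have different lengths", call. = FALSE)
  X
}
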
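# Synthetic data with known ground truth: labelled Gaussian feature tables
# and eight-class fundus-like phantom images.  Every downstream stage of
# the package is exercised on these in the test suite.

# Class means for the informative block: vertices of a regular simplex so
# every pair of classes is separated by the same Euclidean distance.
# Returns a nClasses x nInf matrix with pairwise distance `sep` (exact when
# nInf >= nClasses - 1; otherwise the simplex is projected down and
# rescaled so the *minimum* pairwise distance equals `sep`).
simplex_means <- function(nClasses, nInf, sep) {
  if (nInf == 0L || sep == 0) return(matrix(0, nClasses, max(nInf, 0L)))
  B <- diag(nClasses) - 1 / nClasses            # centred identity, dist sqrt(2)
  sv <- svd(B)
  coords <- sv$u[, seq_len(nClasses - 1L), drop = FALSE] *
    rep(sv$d[seq_len(nClasses - 1L)], each = nClasses)
  # cycle the simplex axes over the informative columns so every
  # informative feature carries class signal, even when nInf exceeds the
  # simplex dimension
  M <- coords[, ((seq_len(nInf) - 1L) %% (nClasses - 1L)) + 1L,
              drop = FALSE]
  d <- stats::dist(M)
  if (min(d) <= .Machine$double.eps) {
    # degenerate projection; spread the classes along the available axes
    M <- matrix(stats::rnorm(nClasses * nInf), nClasses, nInf)
    d <- stats::dist(M)
  }
  M * (sep / min(d))
}

#' Generate a labelled synthetic feature table
#'
#' Produces an `nSamples x nFeatures` Gaussian table whose first
#' `nInformative` columns carry class signal: their class-conditional means
#' sit on a regular simplex with pairwise separation
#' `effectSize * noiseSd`, while all remaining columns are
#' class-independent `N(0, noiseSd^2)` noise.  Class sizes are balanced
#' within one sample and the output is bit-reproducible for a fixed spec.
#'
#' @param spec a [synthTableSpec()] object.
#' @return a list with elements `X` (numeric matrix with columns
#'   `f1..fp`), `y` (factor of class labels `C1..Ck`) and
#'   `informativeMask` (logical vector over columns).
#' @examples
#' tab <- generateFeatureTable(synthTableSpec(nSamples = 60, seed = 7))
#' table(tab$y)
#' @export
generateFeatureTable <- function(spec) {
  stopifnot(is(spec, "SynthTableSpec"))
  validObject(spec)
  n <- spec@nSamples; p <- spec@nFeatures
  k <- spec@nClasses; ninf <- spec@nInformative
  with_seed(stream_seed(spec@seed, "table"), {
    base <- n %/% k
    counts <- rep(base, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    y <- sample(rep(seq_len(k), counts))
    X <- matrix(stats::rnorm(n * p, sd = spec@noiseSd), n, p)
    if (ninf > 0L) {
      M <- simplex_means(k, ninf, spec@effectSize * spec@noiseSd)
      X[, seq_len(ninf)] <- X[, seq_len(ninf), drop = FALSE] +
        M[y, , drop = FALSE]
    }
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X,
         y = factor(paste0("C", y), levels = paste0("C", seq_len(k))),
         informativeMask = seq_len(p) <= ninf)
  })
}

# --------------------------------------------------------------------------
# Phantom fundus images
# --------------------------------------------------------------------------

# Add an isotropic Gaussian blob to an H x W x 3 image (in place semantics
# via return).  Coordinates are in [0, 1], sigma likewise.
add_blob <- function(img, cx, cy, sigma, colour, amp = 1) {
  s <- dim(img)[1L]
  xs <- matrix(seq(0, 1, length.out = s), s, s, byrow = TRUE)
  ys <- matrix(seq(0, 1, length.out = s), s, s)
  g <- amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
  for (ch in 1:3) img[, , ch] <- img[, , ch] + colour[ch] * g
  img
}

# Stamp a polyline (unit coordinates) with given half-thickness (unit) and
# colour, alpha-blended over the image.
stamp_curve <- function(img, px, py, thickness, colour, alpha = 0.85) {
  s <- dim(img)[1L]
  r <- max(1L, ceiling(thickness * s))
  cx <- round(px * (s - 1)) + 1L
  cy <- round(py * (s - 1)) + 1L
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, , drop = FALSE]
  for (j in seq_len(nrow(offs))) {
    xs <- cx + offs$dx[j]; ys <- cy + offs$dy[j]
    ok <- xs >= 1L & xs <= s & ys >= 1L & ys <= s
    if (!any(ok)) next
    idx <- cbind(ys[ok], xs[ok])
    for (ch in 1:3)
      img[, , ch][idx] <- (1 - alpha) * img[, , ch][idx] + alpha * colour[ch]
  }
  img
}

# A vessel arc from the optic disc towards a boundary angle, with optional
# sinusoidal tortuosity.
vessel_path <- function(from, angle, length, wiggleAmp, wiggleFreq, nPts = 160L) {
  t <- seq(0, 1, length.out = nPts)
  dir <- c(cos(angle), sin(angle))
  nrm <- c(-dir[2L], dir[1L])
  wig <- wiggleAmp * sin(wiggleFreq * 2 * pi * t + stats::runif(1, 0, 2 * pi))
  list(x = from[1L] + t * length * dir[1L] + wig * nrm[1L],
       y = from[2L] + t * length * dir[2L] + wig * nrm[2L])
}

# Render one phantom for a given class.  Uses the current RNG state for
# its jitter, so callers control determinism by seeding.
render_phantom <- function(className, size) {
  img <- array(0.04, dim = c(size, size, 3L))
  xs <- matrix(seq(0, 1, length.out = size), size, size, byrow = TRUE)
  ys <- matrix(seq(0, 1, length.out = size), size, size)
  rr <- sqrt((xs - 0.5)^2 + (ys - 0.5)^2)
  field <- rr <= 0.47
  shade <- pmax(0, 1 - 0.9 * (rr / 0.47)^2)
  base <- c(0.58, 0.27, 0.09) * (1 + stats::runif(1, -0.06, 0.06))
  for (ch in 1:3) {
    layer <- img[, , ch]
    layer[field] <- base[ch] * shade[field]
    img[, , ch] <- layer
  }

  discC <- c(0.64, 0.5) + stats::runif(2, -0.03, 0.03)
  discR <- 0.055 * stats::runif(1, 0.9, 1.1)
  nv <- 4L
  tort <- 0.004
  drawDisc <- TRUE

  if (className == "Glaucoma") {        # enlarged, bright disc with deep cup
    discR <- discR * 2.1
  } else if (className == "Hypertension") {  # many tortuous vessels
    nv <- 7L
    tort <- 0.025
  }

  if (drawDisc)
    img <- add_blob(img, discC[1L], discC[2L], discR, c(0.4, 0.35, 0.22))
  if (className == "Glaucoma")          # cup: bright core inside the disc
    img <- add_blob(img, discC[1L], discC[2L], discR * 0.45,
                    c(0.5, 0.45, 0.3))

  angles <- seq(0.6 * pi, 1.4 * pi, length.out = nv) +
    stats::runif(nv, -0.1, 0.1)
  for (a in angles) {
    vp <- vessel_path(discC, a, stats::runif(1, 0.35, 0.45),
                      wiggleAmp = tort * stats::runif(1, 0.8, 1.2),
                      wiggleFreq = if (className == "Hypertension") 5 else 2)
    keep <- sqrt((vp$x - 0.5)^2 + (vp$y - 0.5)^2) <= 0.46
    img <- stamp_curve(img, vp$x[keep], vp$y[keep], 0.012,
                       c(0.30, 0.07, 0.04))
  }

  if (className == "AMD") {             # drusen cluster at the macula
    mac <- c(0.33, 0.5) + stats::runif(2, -0.02, 0.02)
    img <- add_blob(img, mac[1L], mac[2L], 0.10, c(0.35, 0.30, 0.10))
    for (i in seq_len(6L + stats::rpois(1, 2))) {
      off <- stats::runif(2, -0.08, 0.08)
      img <- add_blob(img, mac[1L] + off[1L], mac[2L] + off[2L],
                      0.018, c(0.45, 0.42, 0.18))
    }
  } else if (className == "Diabetes") { # scattered exudates + microhaemorrhages
    for (i in seq_len(10L + stats::rpois(1, 3))) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0.05, 0.38)
      img <- add_blob(img, 0.5 + rad * cos(ang), 0.5 + rad * sin(ang),
                      0.016, c(0.5, 0.48, 0.2))
    }
    for (i in seq_len(6L + stats::rpois(1, 2))) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0.05, 0.38)
      img <- add_blob(img, 0.5 + rad * cos(ang), 0.5 + rad * sin(ang),
                      0.014, c(-0.35, -0.15, -0.05))
    }
  } else if (className == "PM") {       # peripapillary atrophy crescent
    crescC <- discC + c(0.06, 0)
    img <- add_blob(img, crescC[1L], crescC[2L], discR * 1.6,
                    c(0.45, 0.4, 0.3))
    img <- add_blob(img, discC[1L] - 0.02, discC[2L], discR * 1.1,
                    c(-0.35, -0.3, -0.2))
    img <- add_blob(img, 0.42, 0.5, 0.16, c(-0.18, -0.10, -0.02))
  } else if (className == "Other") {    # ring of laser-scar-like dots
    ringR <- 0.28 * stats::runif(1, 0.9, 1.1)
    nd <- 14L
    for (i in seq_len(nd)) {
      a <- 2 * pi * i / nd + stats::runif(1, -0.05, 0.05)
      img <- add_blob(img, 0.5 + ringR * cos(a), 0.5 + ringR * sin(a),
                      0.02, c(0.4, 0.38, 0.25))
    }
  }

  noise <- array(stats::rnorm(size * size, sd = 0.015), c(size, size))
  for (ch in 1:3) img[, , ch] <- img[, , ch] + noise

  if (className == "Cataract") {        # global haze: wash towards grey
    w <- stats::runif(1, 0.45, 0.55)
    for (ch in 1:3) img[, , ch] <- (1 - w) * img[, , ch] + w * 0.72
  }

  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Generate fundus-like phantom images with known class structure
#'
#' Each phantom is a dark circular fundus field with an optic disc and
#' radiating vessels; each class adds a characteristic, jittered
#' structure: an enlarged cupped disc (Glaucoma), global haze (Cataract),
#' scattered bright exudates and dark microhaemorrhage spots (Diabetes),
#' numerous tortuous vessels (Hypertension), a macular drusen cluster
#' (AMD), a peripapillary atrophy crescent (PM), a ring of scar-like dots
#' (Other), or nothing extra (Normal).  Output is pixel-reproducible for a
#' fixed spec.
#'
#' @param spec a [synthImageSpec()] object.
#' @param dir optional directory; when given, images are written as
#'   lossless PNGs under `dir/<class>/<index>.png`.
#' @return a list with `images` (array `size x size x 3 x n`, values in
#'   `[0, 1]`), `labels` (factor) and `sampleIds` (character).
#' @examples
#' ph <- generatePhantomImages(synthImageSpec(nPerClass = 1,
#'   classNames = c("Normal", "Glaucoma"), imageSize = 48))
#' dim(ph$images)
#' @export
generatePhantomImages <- function(spec, dir = NULL) {
  stopifnot(is(spec, "SynthImageSpec"))
  validObject(spec)
  s <- spec@imageSize
  n <- spec@nPerClass * length(spec@classNames)
  imgs <- array(0, dim = c(s, s, 3L, n))
  labels <- character(n)
  ids <- character(n)
  with_seed(stream_seed(spec@seed, "images"), {
    idx <- 0L
    for (cl in spec@classNames) {
      for (i in seq_len(spec@nPerClass)) {
        idx <- idx + 1L
        imgs[, , , idx] <- render_phantom(cl, s)
        labels[idx] <- cl
        ids[idx] <- sprintf("%s_%03d", cl, i)
      }
    }
  })
  labels <- factor(labels, levels = spec@classNames)
  if (!is.null(dir)) {
    for (cl in spec@classNames)
      dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(n)) {
      i_in_class <- sum(labels[seq_len(j)] == labels[j])
      png::writePNG(imgs[, , , j],
                    file.path(dir, as.character(labels[j]),
                              sprintf("%03d.png", i_in_class)))
    }
  }
  list(images = imgs, labels = labels, sampleIds = ids)
}

#' Read a directory-per-class image set
#'
#' Discovers images laid out as `<root>/<class>/<file>.png` and loads them
#' into the array format used by the model functions.
#'
#' @param dir root directory.
#' @return a list with `images`, `labels` and `sampleIds` as in
#'   [generatePhantomImages()].
#' @export
readImageSet <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("no class subdirectories found under ", dir)
  files <- lapply(classes, function(cl)
    sort(list.files(file.path(dir, cl), pattern = "\\.png$",
                    full.names = TRUE)))
  n <- sum(lengths(files))
  if (n == 0L) stop("no PNG images found under ", dir)
  first <- png::readPNG(files[[1L]][1L])
  s <- dim(first)[1L]
  imgs <- array(0, dim = c(s, dim(first)[2L], 3L, n))
  labels <- character(n); ids <- character(n)
  j <- 0L
  for (ci in seq_along(classes)) {
    for (f in files[[ci]]) {
      j <- j + 1L
      a <- png::readPNG(f)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
      imgs[, , , j] <- a[, , 1:3]
      labels[j] <- classes[ci]
      ids[j] <- sprintf("%s/%s", classes[ci], basename(f))
    }
  }
  list(images = imgs, labels = factor(labels, levels = classes),
       sampleIds = ids)
}
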
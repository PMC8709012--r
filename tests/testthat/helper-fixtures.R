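# Shared fixtures and independent oracles, built in code at test time.

# A small separable feature table used across modules.
small_table <- function(seed = 5L, n = 60L, p = 6L, ninf = 2L, k = 2L,
                        effect = 6) {
  generateFeatureTable(synthTableSpec(nSamples = n, nFeatures = p,
                                      nInformative = ninf, nClasses = k,
                                      effectSize = effect, seed = seed))
}

# Tiny model configuration that exercises every layer type.
tiny_config <- function(variant = "rcnn_lstm", nClasses = 2L,
                        inputSize = 12L) {
  modelConfig(nResidualBlocks = 2L, stemFilters = 3L,
              blockFilters = c(4L, 5L), lstmUnits = 6L, fc1Width = 7L,
              nClasses = nClasses, dropoutRate = 0, inputSize = inputSize,
              variant = variant)
}

# Brute-force oracle for the stochastic-neighbour probabilities: direct
# enumeration over all ordered pairs, no shared code with the package.
oracle_nca_P <- function(X, y, w, sigma = 1) {
  n <- nrow(X)
  P <- numeric(n)
  for (i in seq_len(n)) {
    kern <- numeric(n)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sum(w^2 * abs(X[i, ] - X[j, ]))
      kern[j] <- exp(-d / sigma)
    }
    if (sum(kern) > 0)
      P[i] <- sum(kern[y == y[i] & seq_len(n) != i]) / sum(kern)
  }
  P
}

oracle_nca_objective <- function(X, y, w, sigma, lambda) {
  mean(oracle_nca_P(X, y, w, sigma)) - lambda * sum(w^2)
}

# Brute-force ReliefF oracle: literal double loop over the update rule
# with range-normalised differences, Manhattan neighbour distance and
# lowest-index tie-breaking.
oracle_relieff <- function(X, y, k) {
  y <- factor(y)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  norm1 <- function(a, u, v) if (rng[a] > 0) abs(u[a] - v[a]) / rng[a] else 0
  manh <- function(u, v)
    sum(vapply(seq_len(p), function(a) norm1(a, u, v), numeric(1)))
  priors <- table(y) / n
  W <- numeric(p)
  for (i in seq_len(n)) {
    dists <- vapply(seq_len(n), function(j) manh(X[i, ], X[j, ]), numeric(1))
    for (a in seq_len(p)) {
      hitIdx <- setdiff(which(y == y[i]), i)
      hits <- hitIdx[order(dists[hitIdx], hitIdx)][seq_len(k)]
      hitTerm <- sum(vapply(hits, function(j) norm1(a, X[i, ], X[j, ]),
                            numeric(1))) / (n * k)
      missTerm <- 0
      for (cl in setdiff(levels(y), as.character(y[i]))) {
        cIdx <- which(y == cl)
        kk <- min(k, length(cIdx))
        miss <- cIdx[order(dists[cIdx], cIdx)][seq_len(kk)]
        missTerm <- missTerm +
          (priors[[cl]] / (1 - priors[[as.character(y[i])]])) *
          sum(vapply(miss, function(j) norm1(a, X[i, ], X[j, ]),
                     numeric(1))) / (n * k)
      }
      W[a] <- W[a] - hitTerm + missTerm
    }
  }
  W
}
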
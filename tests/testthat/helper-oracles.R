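# Independent brute-force oracles used to pin down expected values.
# These deliberately use scalar double loops, not the package's vectorized
# code paths.

oracle_distance <- function(xi, xj, metric) {
  switch(metric,
    euclidean = sqrt(sum((xi - xj)^2)),
    cosine = 1 - sum(xi * xj) / (sqrt(sum(xi^2)) * sqrt(sum(xj^2))),
    correlation = 1 - stats::cor(xi, xj))
}

oracle_pairwise <- function(X, metric = "euclidean") {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) D[i, j] <- oracle_distance(X[i, ], X[j, ], metric)
  }
  D
}

oracle_stress <- function(DX, DY, W = NULL) {
  n <- nrow(DX)
  if (is.null(W)) W <- matrix(1, n, n)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    total <- total + W[i, j] * (DX[i, j] - DY[i, j])^2
  }
  total
}

oracle_pair_loss <- function(Xb, Yb, metric = "euclidean") {
  b <- nrow(Xb)
  total <- 0
  for (i in seq_len(b - 1L)) for (j in (i + 1L):b) {
    dx <- oracle_distance(Xb[i, ], Xb[j, ], metric)
    dy <- sqrt(sum((Yb[i, ] - Yb[j, ])^2))
    total <- total + (dx - dy)^2
  }
  total
}

# Least squares via normal equations with a pseudo-inverse (generic route,
# independent of the SVD construction under test).
oracle_least_squares <- function(X, Y) {
  XtX <- crossprod(X)
  eg <- eigen(XtX, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  pinv <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  pinv %*% crossprod(X, Y)
}

# Best 1-D (or k-D) configuration for a small distance matrix by
# multi-restart numerical minimization of the ordered-pair stress.
oracle_mds_config <- function(D, k, restarts = 50, seed = 42) {
  n <- nrow(D)
  best <- Inf
  set.seed(seed)
  for (r in seq_len(restarts)) {
    y0 <- stats::rnorm(n * k)
    res <- stats::optim(y0, function(y) {
      sum((D - as.matrix(stats::dist(matrix(y, n, k))))^2)
    }, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, res$value)
  }
  best
}

rand_matrix <- function(n, m, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * m), n, m)
}

# Random matrix with a prescribed exact rank.
rand_rank_matrix <- function(n, m, r, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * r), n, r) %*% matrix(stats::rnorm(r * m), r, m)
}
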
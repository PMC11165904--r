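#' Pairwise distance matrix under a named metric
#'
#' Computes the full symmetric matrix of pairwise dissimilarities between the
#' rows of an observation-by-feature matrix. Three metrics are supported:
#' `"euclidean"` (the L2 norm of the row difference), `"cosine"`
#' (one minus the cosine similarity) and `"correlation"` (one minus the
#' Pearson correlation of the two rows).
#'
#' Dense distance matrices grow quadratically with the number of rows, so the
#' computation refuses inputs with more than `max_n` rows; see
#' [estimate_stress()] for a pair-sampled alternative at large n.
#'
#' @param X numeric matrix (rows = observations, columns = features), dense or
#'   sparse; all values must be finite.
#' @param metric one of `"euclidean"`, `"cosine"`, `"correlation"`.
#' @param max_n maximum number of rows for which an n x n matrix is
#'   materialized (default 20000).
#' @return an n x n symmetric numeric matrix with zero diagonal and
#'   nonnegative entries; the metric name is attached as attribute `"metric"`.
#' @examples
#' pairwise_distances(rbind(c(0, 0), c(3, 4)))  # 3-4-5 triangle
#' @export
pairwise_distances <- function(X, metric = c("euclidean", "cosine", "correlation"),
                               max_n = 20000L) {
  metric <- match.arg(metric)
  X <- as_dense_matrix(X)
  n <- nrow(X)
  if (n > max_n) {
    stop(sprintf(paste0("n = %d rows would require a dense %d x %d distance ",
                        "matrix; the cap is max_n = %d. Use estimate_stress() ",
                        "for sampled-pair stress at this scale."),
                 n, n, n, max_n), call. = FALSE)
  }
  D <- switch(metric,
    euclidean = as.matrix(stats::dist(X, method = "euclidean")),
    cosine = {
      norms <- sqrt(rowSums(X^2))
      if (any(norms == 0)) {
        stop("cosine distance is undefined for all-zero rows (rows: ",
             paste(which(norms == 0), collapse = ", "), ")", call. = FALSE)
      }
      S <- tcrossprod(X / norms)
      1 - S
    },
    correlation = {
      if (ncol(X) < 2L) {
        stop("correlation distance needs at least two features", call. = FALSE)
      }
      sds <- apply(X, 1L, stats::sd)
      if (any(sds == 0)) {
        stop("correlation distance is undefined for constant rows (rows: ",
             paste(which(sds == 0), collapse = ", "), ")", call. = FALSE)
      }
      1 - stats::cor(t(X))
    }
  )
  # numeric cleanup: exact symmetry, zero diagonal, clamp tiny negatives
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D[D < 0] <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  attr(D, "metric") <- metric
  D
}

#' Metric-MDS stress between two distance matrices
#'
#' The raw stress objective
#' \deqn{\sigma(D_X, D_Y) = \sum_{i,j} w_{ij} ((D_X)_{ij} - (D_Y)_{ij})^2,}
#' summed over all ordered pairs (both triangles plus the zero diagonal), so
#' that with unit weights it equals the squared Frobenius norm
#' \eqn{\|D_X - D_Y\|_F^2}.
#'
#' @param DX,DY n x n distance matrices of identical shape.
#' @param weights optional n x n symmetric nonnegative weight matrix
#'   (default: all ones). See [sammon_weights()] for the Sammon preset.
#' @return a single nonnegative number.
#' @export
stress <- function(DX, DY, weights = NULL) {
  DX <- as_dense_matrix(DX, "DX")
  DY <- as_dense_matrix(DY, "DY")
  if (!identical(dim(DX), dim(DY))) {
    stop("`DX` and `DY` must have identical dimensions", call. = FALSE)
  }
  R2 <- (DX - DY)^2
  if (is.null(weights)) return(sum(R2))
  W <- check_square_symmetric(weights, "weights")
  if (!identical(dim(W), dim(DX))) {
    stop("`weights` must have the same dimensions as `DX`", call. = FALSE)
  }
  if (any(W < 0)) stop("`weights` must be nonnegative", call. = FALSE)
  sum(W * R2)
}

#' Sammon-style stress weights
#'
#' Weight preset \eqn{w_{ij} = 1/(D_X)_{ij}} with \eqn{w_{ii} = 0}, which
#' emphasizes the preservation of small distances.
#'
#' @param DX an input-space distance matrix.
#' @return an n x n weight matrix usable in [stress()].
#' @export
sammon_weights <- function(DX) {
  DX <- check_square_symmetric(DX, "DX")
  W <- ifelse(DX > 0, 1 / DX, 0)
  diag(W) <- 0
  W
}

#' Center the rows of a data matrix
#'
#' Subtracts the column means so that every feature sums to zero across
#' observations; pairwise Euclidean distances are unchanged.
#'
#' @param X numeric observation-by-feature matrix.
#' @return the centered matrix.
#' @export
center_rows <- function(X) {
  X <- as_dense_matrix(X)
  sweep(X, 2L, colMeans(X), "-")
}

#' SVD-based intrinsic dimension estimate
#'
#' The smallest number h of top singular values of the row-centered matrix
#' whose squared mass reaches at least `variance_threshold` of the total:
#' \eqn{\sum_{i \le h} \sigma_i^2 / \sum_i \sigma_i^2 \ge} threshold. Used to
#' size the hidden layer of the neural embedding.
#'
#' @param X numeric observation-by-feature matrix; must not be identically
#'   zero after centering.
#' @param variance_threshold fraction of squared singular-value mass to
#'   retain, in (0, 1]; default 0.95.
#' @return a positive integer.
#' @export
intrinsic_dimension <- function(X, variance_threshold = 0.95) {
  if (!is.numeric(variance_threshold) || length(variance_threshold) != 1L ||
      variance_threshold <= 0 || variance_threshold > 1) {
    stop("`variance_threshold` must be a single number in (0, 1]", call. = FALSE)
  }
  Xc <- center_rows(X)
  d <- svd(Xc, nu = 0L, nv = 0L)$d
  total <- sum(d^2)
  if (total == 0) {
    stop("matrix is zero after row centering; intrinsic dimension undefined",
         call. = FALSE)
  }
  as.integer(which(cumsum(d^2) / total >= variance_threshold - 1e-12)[1L])
}

#' Gram matrix from squared Euclidean distances (double centering)
#'
#' Applies the double-centering map \eqn{-\frac{1}{2} H D^2 H} with
#' \eqn{H = I - \frac{1}{n} e e^\top}. When `D2` holds the squared Euclidean
#' distances of a row-centered matrix X, the result is the n x n Gram matrix
#' of the rows of X. This identity links classical MDS to PCA.
#'
#' @param D2 n x n symmetric matrix of elementwise-squared Euclidean
#'   distances with zero diagonal.
#' @return an n x n symmetric matrix.
#' @export
gram_from_distances <- function(D2) {
  D2 <- check_square_symmetric(D2, "D2")
  # H A H subtracts row means, column means and adds back the grand mean
  rm_ <- rowMeans(D2)
  gm <- mean(D2)
  G <- -0.5 * (D2 - outer(rm_, rep(1, ncol(D2))) -
                 outer(rep(1, nrow(D2)), rm_) + gm)
  (G + t(G)) / 2
}

#' Sampled-pair stress estimate for large data
#'
#' Estimates the normalized stress of an embedding without materializing the
#' dense distance matrices: `n_pairs` ordered pairs are drawn uniformly with
#' replacement and the mean squared distance error is rescaled to the full
#' ordered-pair sum. The result is an estimate and is labeled as such.
#'
#' @param X input observation-by-feature matrix.
#' @param Y embedding matrix with the same number of rows.
#' @param metric input-space metric, as in [pairwise_distances()].
#' @param n_pairs number of sampled ordered pairs (default 100000).
#' @param seed RNG seed for the pair sample.
#' @return a list with `estimate` (rescaled stress), `n_pairs`, and
#'   `is_estimate = TRUE`.
#' @export
estimate_stress <- function(X, Y, metric = "euclidean", n_pairs = 1e5, seed = 1L) {
  X <- as_dense_matrix(X)
  Y <- as_dense_matrix(Y, "Y")
  n <- nrow(X)
  if (nrow(Y) != n) stop("`X` and `Y` must have the same number of rows", call. = FALSE)
  ij <- with_seed(seed, cbind(sample.int(n, n_pairs, replace = TRUE),
                              sample.int(n, n_pairs, replace = TRUE)))
  dx <- row_pair_distances(X, ij[, 1L], ij[, 2L], metric)
  dy <- sqrt(rowSums((Y[ij[, 1L], , drop = FALSE] - Y[ij[, 2L], , drop = FALSE])^2))
  list(estimate = mean((dx - dy)^2) * as.numeric(n)^2,
       n_pairs = n_pairs, is_estimate = TRUE)
}

# Distances between selected row pairs without a dense matrix.
row_pair_distances <- function(X, i, j, metric) {
  A <- X[i, , drop = FALSE]
  B <- X[j, , drop = FALSE]
  switch(metric,
    euclidean = sqrt(rowSums((A - B)^2)),
    cosine = {
      na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
      if (any(na == 0 | nb == 0)) {
        stop("cosine distance is undefined for all-zero rows", call. = FALSE)
      }
      pmax(0, 1 - rowSums(A * B) / (na * nb))
    },
    correlation = {
      A <- A - rowMeans(A); B <- B - rowMeans(B)
      na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
      if (any(na == 0 | nb == 0)) {
        stop("correlation distance is undefined for constant rows", call. = FALSE)
      }
      pmax(0, 1 - rowSums(A * B) / (na * nb))
    },
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  )
}
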
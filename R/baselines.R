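#' SMACOF: metric MDS by stress majorization
#'
#' Minimizes the (unweighted) raw stress by iterating the Guttman transform,
#' the closed-form configuration update of the SMACOF majorization scheme.
#' The stress sequence is guaranteed non-increasing. Zero distances in the
#' current configuration contribute 0/0 terms to the transform; these are
#' defined as 0.
#'
#' The dense implementation is capped at `max_n` points: per-iteration cost
#' and memory are quadratic in n.
#'
#' @param D n x n symmetric nonnegative distance matrix with zero diagonal.
#' @param k target dimension.
#' @param max_iter maximum number of majorization iterations (default 300).
#' @param tol convergence threshold on the relative stress decrease per
#'   iteration (default 1e-6).
#' @param seed RNG seed (used only for `init = "random"`).
#' @param init `"classical"` (default) starts from the classical-MDS
#'   configuration via [gram_from_distances()]; `"random"` from standard
#'   normal coordinates.
#' @param max_n refuse dense operation above this many points (default 20000).
#' @return a list with `embedding` (n x k), `stress` (final ordered-pair
#'   stress), `trace` (stress after each iteration, starting at the initial
#'   configuration) and `iterations`.
#' @export
smacof_embed <- function(D, k, max_iter = 300L, tol = 1e-6, seed = 1L,
                         init = c("classical", "random"), max_n = 20000L) {
  init <- match.arg(init)
  D <- check_square_symmetric(D, "D")
  n <- nrow(D)
  if (n > max_n) {
    stop(sprintf("SMACOF is quadratic in n; n = %d exceeds the cap max_n = %d",
                 n, max_n), call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(D < 0)) stop("`D` must be nonnegative", call. = FALSE)
  if (any(diag(D) != 0)) stop("`D` must have a zero diagonal", call. = FALSE)

  Y <- switch(init,
    classical = classical_config(D, k),
    random = with_seed(seed, matrix(stats::rnorm(n * k), n, k))
  )
  DY <- as.matrix(stats::dist(Y))
  s <- sum((D - DY)^2)
  trace <- s
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # Guttman transform with unit weights: Y <- (1/n) B(Y) Y,
    # B_ij = -D_ij / DY_ij off-diagonal (0 where DY_ij = 0), diag = -rowsums.
    B <- -D / DY
    B[DY == 0] <- 0
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Ynew <- B %*% Y / n
    DY <- as.matrix(stats::dist(Ynew))
    snew <- sum((D - DY)^2)
    Y <- Ynew
    trace <- c(trace, snew)
    if (s > 0 && (s - snew) / s < tol) {
      s <- snew
      break
    }
    s <- snew
    if (s == 0) break
  }
  list(embedding = Y, stress = s, trace = trace, iterations = iter)
}

# Classical-MDS configuration of a distance matrix: top-k spectral
# coordinates of the double-centered squared distances.
classical_config <- function(D, k) {
  G <- gram_from_distances(D^2)
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(eg$values[seq_len(k)], 0)
  Y <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  Y
}

#' Classical MDS / PCA embedding with an explicit linear map
#'
#' Row-centers the input and projects it onto the top-k right singular
#' vectors. For explicitly given points this solves classical MDS, and the
#' returned loading matrix maps unseen points into the same space:
#' `sweep(X_new, 2, fit$center) %*% fit$loadings`.
#'
#' @param X numeric observation-by-feature matrix.
#' @param k target dimension, at most `min(n, m)`.
#' @return a list with `embedding` (n x k), `loadings` (m x k), `center`
#'   (column means) and `sdev` (singular values / sqrt(n - 1)).
#' @export
pca_embed <- function(X, k) {
  X <- as_dense_matrix(X)
  if (k > min(dim(X))) {
    stop(sprintf("`k` = %d exceeds min(n, m) = %d", k, min(dim(X))), call. = FALSE)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sv <- svd(Xc, nu = k, nv = k)
  emb <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(emb) <- rownames(X)
  list(embedding = emb, loadings = sv$v, center = ctr,
       sdev = sv$d / sqrt(max(nrow(X) - 1, 1)))
}

#' Map new observations through a PCA embedding
#'
#' @param fit the list returned by [pca_embed()].
#' @param X_new matrix with the same number of columns as the training data.
#' @return an n_new x k embedding matrix.
#' @export
pca_transform <- function(fit, X_new) {
  X_new <- as_dense_matrix(X_new, "X_new")
  if (ncol(X_new) != length(fit$center)) {
    stop("`X_new` has the wrong number of columns", call. = FALSE)
  }
  sweep(X_new, 2L, fit$center, "-") %*% fit$loadings
}

#' Gaussian random projection
#'
#' Projects the rows of X with an m x k matrix of i.i.d. N(0, 1/k) entries.
#' The 1/sqrt(k) scaling preserves squared Euclidean distances in
#' expectation, and by the Johnson-Lindenstrauss lemma the distortion of all
#' pairwise distances is bounded with high probability when
#' k = O(log n / eps^2).
#'
#' @param X numeric observation-by-feature matrix.
#' @param k target dimension.
#' @param seed RNG seed; the projection matrix is a pure function of
#'   (m, k, seed).
#' @return a list with `embedding` (n x k) and `projection` (m x k), the
#'   latter reusable for unseen points via `X_new %*% projection`.
#' @export
random_projection <- function(X, k, seed = 1L) {
  X <- as_dense_matrix(X)
  if (k < 1L) stop("`k` must be positive", call. = FALSE)
  m <- ncol(X)
  R <- with_seed(seed, matrix(stats::rnorm(m * k), m, k) / sqrt(k))
  emb <- X %*% R
  rownames(emb) <- rownames(X)
  list(embedding = emb, projection = R)
}
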
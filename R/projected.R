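#' Closed-form least-squares linear projection onto a target embedding
#'
#' Given data X (n x m) and a candidate embedding Y (n x k), finds the
#' matrix P minimizing \eqn{\|Y - XP\|_F^2} via the thin SVD of X restricted
#' to its nonzero singular values:
#' \deqn{P = V_1 \Sigma^{-1} U_1^\top Y,}
#' a pseudo-inverse construction that handles rank deficiency. The attained
#' residual equals \eqn{\|U_2^\top Y\|_F^2}, the mass of Y outside the column
#' space of X; both are returned.
#'
#' @param X numeric n x m data matrix.
#' @param Y_tilde numeric n x k target embedding.
#' @param rank_tol tolerance deciding which singular values count as nonzero;
#'   default `sigma_1 * max(n, m) * .Machine$double.eps`.
#' @return a list with `P` (m x k), `residual` (\eqn{\|Y - XP\|_F^2},
#'   computed as \eqn{\|U_2^\top Y\|_F^2}) and `rank` (the numerical rank r).
#' @export
least_squares_projection <- function(X, Y_tilde, rank_tol = NULL) {
  X <- as_dense_matrix(X)
  Y <- as_dense_matrix(Y_tilde, "Y_tilde")
  n <- nrow(X); m <- ncol(X)
  if (nrow(Y) != n) stop("`X` and `Y_tilde` must have the same number of rows",
                         call. = FALSE)
  sv <- svd(X, nu = n, nv = m)
  d <- sv$d
  if (is.null(rank_tol)) rank_tol <- d[1L] * max(n, m) * .Machine$double.eps
  r <- sum(d > rank_tol)
  if (r == 0L) {
    return(list(P = matrix(0, m, ncol(Y)), residual = sum(Y^2), rank = 0L))
  }
  U1 <- sv$u[, seq_len(r), drop = FALSE]
  V1 <- sv$v[, seq_len(r), drop = FALSE]
  P <- V1 %*% (crossprod(U1, Y) / d[seq_len(r)])
  residual <- if (r < n) {
    U2 <- sv$u[, (r + 1L):n, drop = FALSE]
    sum(crossprod(U2, Y)^2)
  } else 0
  list(P = P, residual = residual, rank = as.integer(r))
}

#' Projected metric MDS: the best linear map under the stress objective
#'
#' Solves \eqn{\min_P \|D_X - D_{XP}\|_F^2}, metric MDS constrained to a
#' linear map Y = XP. The objective is made differentiable at coincident
#' points by smoothing each output distance to \eqn{\sqrt{\|\cdot\|^2 +
#' \epsilon}}, and minimized by a quasi-Newton (L-BFGS) method with an
#' analytic gradient, starting from the PCA loading matrix. Since the
#' optimizer starts at the PCA solution, the returned map never has higher
#' stress than PCA.
#'
#' @param X numeric observation-by-feature matrix; rows are centered
#'   internally (centering leaves the input distances unchanged and keeps
#'   the embedding centered for any P).
#' @param k target dimension.
#' @param epsilon distance-smoothing constant (default 1e-6).
#' @param max_iter maximum quasi-Newton iterations (default 500).
#' @param seed RNG seed (kept for interface symmetry; the solver is
#'   deterministic from its PCA start).
#' @param max_n refuse dense operation above this many points.
#' @return a list with `P` (m x k), `embedding` (centered X times P),
#'   `objective` (final unsmoothed stress \eqn{\|D_X - D_{XP}\|_F^2}),
#'   `trace` (best smoothed objective after each function evaluation, a
#'   non-increasing sequence), `center` (column means removed from X) and
#'   `convergence` (optim status).
#' @export
solve_projected_mmds <- function(X, k, epsilon = 1e-6, max_iter = 500L,
                                 seed = 1L, max_n = 20000L) {
  X <- as_dense_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (n > max_n) {
    stop(sprintf("dense distance matrices above max_n = %d are refused", max_n),
         call. = FALSE)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  DX <- as.matrix(stats::dist(Xc))
  P0 <- pca_embed(Xc, k)$loadings

  eval_env <- new.env()
  eval_env$best <- Inf
  eval_env$trace <- numeric(0)

  fn <- function(p) {
    P <- matrix(p, m, k)
    SQ <- as.matrix(stats::dist(Xc %*% P))^2
    Deps <- sqrt(SQ + epsilon)
    diag(Deps) <- 0
    val <- sum((DX - Deps)^2)
    eval_env$best <- min(eval_env$best, val)
    eval_env$trace <- c(eval_env$trace, eval_env$best)
    val
  }
  gr <- function(p) {
    P <- matrix(p, m, k)
    Y <- Xc %*% P
    SQ <- as.matrix(stats::dist(Y))^2
    Deps <- sqrt(SQ + epsilon)
    A <- 2 * (Deps - DX) / Deps
    diag(A) <- 0
    gY <- 2 * (rowSums(A) * Y - A %*% Y)
    as.vector(crossprod(Xc, gY))
  }

  # factr scales relative convergence in units of machine epsilon
  opt <- stats::optim(as.vector(P0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter,
                                     factr = 1e-8 / .Machine$double.eps))
  P <- matrix(opt$par, m, k)

  # keep the better of the start and the optimizer output (majorization-free
  # solvers can in principle end on a line-search failure)
  obj_of <- function(P) sum((DX - as.matrix(stats::dist(Xc %*% P)))^2)
  if (obj_of(P) > obj_of(P0)) P <- P0

  emb <- Xc %*% P
  rownames(emb) <- rownames(X)
  list(P = P, embedding = emb, objective = obj_of(P),
       trace = eval_env$trace, center = ctr, convergence = opt$convergence)
}

#' Approximation-bound diagnostic for linear-map embeddings
#'
#' For row-centered data X and any candidate embedding Y, the closed-form
#' projection P of [least_squares_projection()] satisfies
#' \deqn{\|D_{Y} - D_{XP}\|_F \le \sqrt{n - r + 2}\, \|D_{Y}\|_F,}
#' with r the numerical rank of X. This is the constructive inequality
#' behind the guarantee that the best linear map's stress is within a
#' \eqn{\sqrt{n - r + 2}\,\|D_Y\|_F} additive term of any embedding's stress.
#' The function computes both sides and reports whether the bound holds.
#'
#' @param X numeric data matrix; rows are centered internally if needed.
#' @param Y_tilde any candidate n x k embedding.
#' @return a list with `lhs`, `rhs`, `holds`, `rank` and `P`.
#' @export
projection_bound_check <- function(X, Y_tilde) {
  X <- center_rows(X)
  Y <- as_dense_matrix(Y_tilde, "Y_tilde")
  n <- nrow(X)
  ls <- least_squares_projection(X, Y)
  DY <- as.matrix(stats::dist(Y))
  DXP <- as.matrix(stats::dist(X %*% ls$P))
  lhs <- sqrt(sum((DY - DXP)^2))
  rhs <- sqrt(n - ls$rank + 2) * sqrt(sum(DY^2))
  list(lhs = lhs, rhs = rhs,
       holds = lhs <= rhs * (1 + 1e-10) + 1e-12,
       rank = ls$rank, P = ls$P)
}
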
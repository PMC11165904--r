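test_that("pairwise distances match hand values and the double-loop oracle", {
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4))),
               matrix(c(0, 5, 5, 0), 2), ignore_attr = TRUE)
  expect_equal(pairwise_distances(rbind(c(1, 0), c(0, 1)), "cosine"),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  X <- rand_matrix(20, 5, seed = 11)
  for (metric in c("euclidean", "cosine", "correlation")) {
    D <- pairwise_distances(X, metric)
    expect_lt(max(abs(D - oracle_pairwise(X, metric))), 1e-10)
    expect_identical(attr(D, "metric"), metric)
    expect_true(isSymmetric(unname(`attr<-`(D, "metric", NULL))))
    expect_true(all(diag(D) == 0) && all(D >= 0))
  }
})

test_that("degenerate rows raise explicit errors under cosine/correlation", {
  X <- rbind(c(0, 0, 0), c(1, 2, 3))
  expect_error(pairwise_distances(X, "cosine"), "all-zero")
  expect_error(pairwise_distances(rbind(c(2, 2, 2), c(1, 2, 3)), "correlation"),
               "constant")
  expect_error(pairwise_distances(matrix(NaN, 2, 2)), "finite")
})

test_that("dense distance matrices are refused above the size cap", {
  X <- rand_matrix(30, 2, seed = 1)
  expect_error(pairwise_distances(X, max_n = 20), "cap")
  expect_silent(pairwise_distances(X, max_n = 30))
})

test_that("euclidean distances satisfy the triangle inequality on sampled triples", {
  X <- rand_matrix(40, 6, seed = 7)
  D <- pairwise_distances(X)
  set.seed(8)
  for (rep in 1:200) {
    ijk <- sample.int(40, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("stress matches hand values, the oracle, and its invariants", {
  D5 <- matrix(c(0, 5, 5, 0), 2)
  D3 <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(stress(D5, D5), 0)
  expect_equal(stress(D5, D3), 8)  # both ordered pairs: 2 * (5-3)^2

  set.seed(21)
  A <- pairwise_distances(rand_matrix(10, 4, seed = 1))
  B <- pairwise_distances(rand_matrix(10, 4, seed = 2))
  W <- abs(rand_matrix(10, 10, seed = 3)); W <- (W + t(W)) / 2
  expect_equal(stress(A, B), oracle_stress(A, B))
  expect_equal(stress(A, B, W), oracle_stress(A, B, W))
  expect_equal(stress(A, B), stress(B, A))   # symmetric in its arguments
  expect_gte(stress(A, B), 0)
  expect_equal(stress(A, B), sum((A - B)^2))  # Frobenius identity
})

test_that("stress validates shapes and weights", {
  D <- matrix(0, 3, 3)
  expect_error(stress(D, matrix(0, 2, 2)), "dimensions")
  W <- matrix(-1, 3, 3)
  expect_error(stress(D, D, W), "nonnegative")
  expect_error(stress(D, D, matrix(runif(9), 3, 3)), "symmetric")
})

test_that("sammon weights are the inverse input distances with zero diagonal", {
  D <- pairwise_distances(rand_matrix(6, 3, seed = 5))
  W <- sammon_weights(D)
  off <- upper.tri(D)
  expect_equal(W[off], 1 / D[off])
  expect_true(all(diag(W) == 0))
})

test_that("center_rows removes column means and is idempotent", {
  expect_equal(center_rows(rbind(c(1, 2), c(3, 4))),
               rbind(c(-1, -1), c(1, 1)))
  X <- rand_matrix(30, 7, seed = 13)
  Xc <- center_rows(X)
  expect_lt(max(abs(colSums(Xc))), 1e-9)
  expect_equal(center_rows(Xc), Xc)
})

test_that("intrinsic dimension follows the cumulative singular-value ratio", {
  line <- outer(seq(-2, 2, length.out = 10), c(1, 2, 3))  # rank 1
  expect_identical(intrinsic_dimension(line), 1L)

  # singular values (1, 1): half the mass each, so 0.95 needs both
  X2 <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) / sqrt(2)
  expect_identical(intrinsic_dimension(X2), 2L)

  X <- rand_matrix(50, 10, seed = 17)
  d <- svd(scale(X, scale = FALSE))$d
  expected <- which(cumsum(d^2) / sum(d^2) >= 0.95)[1]
  expect_identical(intrinsic_dimension(X), as.integer(expected))
  expect_error(intrinsic_dimension(matrix(0, 3, 3)), "zero")
})

test_that("double centering squared distances recovers the row Gram matrix", {
  expect_equal(gram_from_distances(matrix(c(0, 4, 4, 0), 2)),
               matrix(c(1, -1, -1, 1), 2))
  expect_equal(gram_from_distances(matrix(0, 3, 3)), matrix(0, 3, 3))

  X <- center_rows(rand_matrix(15, 4, seed = 19))
  D2 <- pairwise_distances(X)^2
  expect_lt(max(abs(gram_from_distances(D2) - tcrossprod(X))), 1e-9)
  expect_error(gram_from_distances(matrix(1:9, 3, 3)), "symmetric")
})

test_that("centered-data distance mass identity holds across random shapes", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(2:200, 1); m <- sample(1:50, 1)
    X <- center_rows(matrix(rnorm(n * m), n, m))
    lhs <- sum(pairwise_distances(X)^2)
    rhs <- 2 * n * sum(X^2)
    expect_lt(abs(lhs - rhs), 1e-8 * max(rhs, 1))
  }
})

test_that("sampled-pair stress estimate tracks the exact stress", {
  X <- rand_matrix(150, 5, seed = 23)
  Y <- pca_embed(X, 2)$embedding
  exact <- stress(pairwise_distances(X), pairwise_distances(Y))
  est <- estimate_stress(X, Y, n_pairs = 2e5, seed = 9)
  expect_true(est$is_estimate)
  expect_lt(abs(est$estimate - exact) / exact, 0.1)
})
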
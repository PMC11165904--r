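test_that("network initialization is seeded and symmetric-uniform", {
  a <- init_network(5, 3, 2, seed = 1)
  b <- init_network(5, 3, 2, seed = 1)
  c <- init_network(5, 3, 2, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a$W1, c$W1))
  expect_equal(dim(a$W1), c(5L, 3L))
  expect_equal(dim(a$W2), c(3L, 2L))
  expect_true(all(a$b1 == 0) && all(a$b2 == 0))
  lim <- sqrt(6 / (5 + 3))
  expect_true(all(abs(a$W1) <= lim))
  expect_error(init_network(0, 3, 2), "positive")
})

test_that("batch pair loss matches hand values and the pair-loop oracle", {
  # two points, input distance 5, output distance 3
  expect_equal(batch_pair_loss(rbind(c(0, 0), c(3, 4)), rbind(0, 3)), 4)

  # equal output rows: loss collapses to the sum of squared input distances
  Xb <- rand_matrix(6, 4, seed = 3)
  Yb0 <- matrix(1, 6, 2)
  DX <- pairwise_distances(Xb)
  expect_equal(batch_pair_loss(Xb, Yb0), sum(DX[upper.tri(DX)]^2))

  Xb <- rand_matrix(16, 5, seed = 4)
  Yb <- rand_matrix(16, 2, seed = 5)
  for (metric in c("euclidean", "cosine", "correlation")) {
    expect_equal(batch_pair_loss(Xb, Yb, metric),
                 oracle_pair_loss(Xb, Yb, metric))
  }
  expect_error(batch_pair_loss(Xb[1, , drop = FALSE], Yb[1, , drop = FALSE]),
               "at least 2")
})

test_that("two points are embedded exactly and training is seed-deterministic", {
  X <- rbind(c(0, 0), c(3, 4))
  fit <- nn_mmds(X, 1, epochs = 400, batch_size = 2, seed = 1)
  DX <- pairwise_distances(X)
  s <- stress(DX, pairwise_distances(fit$embedding))
  expect_lt(s / sum(DX^2), 1e-3)

  ds <- gaussian_clusters(60, 8, 3, separation = 8, seed = 2)
  f1 <- nn_mmds(ds$X, 2, epochs = 20, batch_size = 32, seed = 5)
  f2 <- nn_mmds(ds$X, 2, epochs = 20, batch_size = 32, seed = 5)
  f3 <- nn_mmds(ds$X, 2, epochs = 20, batch_size = 32, seed = 6)
  expect_identical(f1$embedding, f2$embedding)
  expect_false(identical(f1$embedding, f3$embedding))
})

test_that("training reduces the loss and the trace is recorded per epoch", {
  box <- open_box(300, seed = 0)
  fit <- nn_mmds(box$X, 2, epochs = 60, seed = 0)
  expect_length(fit$loss_trace, 60)
  expect_lt(fit$loss_trace[60], fit$loss_trace[1])
  # non-increasing when smoothed over 10-epoch windows
  smoothed <- vapply(seq(10, 60, 10), function(e) mean(fit$loss_trace[(e - 9):e]),
                     numeric(1))
  expect_true(all(diff(smoothed) <= 1e-8))
})

test_that("auto hidden size composes with the intrinsic dimension and k floor", {
  line <- outer(seq(-1, 1, length.out = 30), c(2, 1, -1))  # rank 1
  expect_identical(intrinsic_dimension(line), 1L)
  fit <- nn_mmds(line, 2, epochs = 5, batch_size = 16, seed = 1)
  # intrinsic dimension 1 < k = 2, so the bottleneck is raised to k
  expect_gte(fit$config$hidden, 2L)
  expect_identical(fit$model$h, fit$config$hidden)
})

test_that("transform is a pure forward pass consistent with training", {
  ds <- gaussian_clusters(80, 6, 2, separation = 8, seed = 3)
  fit <- nn_mmds(ds$X, 2, epochs = 30, batch_size = 32, seed = 7,
                 standardize = TRUE)
  expect_identical(predict(fit, ds$X), fit$embedding)
  # batch independence: single-row transform equals the batched row
  one <- predict(fit, ds$X[5, , drop = FALSE])
  expect_equal(as.numeric(one), as.numeric(fit$embedding[5, ]))
  expect_error(predict(fit, ds$X[, 1:3]), "columns")
})

test_that("out-of-sample stress stays close to the training stress", {
  ds <- gaussian_clusters(400, 10, 3, separation = 8, seed = 11)
  idx <- with(list(), {set.seed(11); sample.int(400, 280)})
  Xtr <- ds$X[idx, ]; Xte <- ds$X[-idx, ]
  fit <- nn_mmds(Xtr, 2, epochs = 300, seed = 11)
  ratio_of <- function(X, Y) {
    DX <- pairwise_distances(X)
    stress(DX, pairwise_distances(Y)) / sum(DX^2)
  }
  r_train <- ratio_of(Xtr, fit$embedding)
  r_test <- ratio_of(Xte, predict(fit, Xte))
  expect_lt(r_test, 1.5 * r_train)
})

test_that("model serialization round-trips predictions bit-for-bit", {
  ds <- gaussian_clusters(50, 5, 2, separation = 6, seed = 1)
  fit <- nn_mmds(ds$X, 2, epochs = 10, batch_size = 25, seed = 3,
                 standardize = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_nn_model(fit, path)
  back <- read_nn_model(path)
  expect_identical(predict(back, ds$X), unname(fit$embedding))

  # newer major version fails loudly
  obj <- jsonlite::read_json(path)
  obj$version <- "2.0"
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_nn_model(path), "version")
})

test_that("average_loss rescales the first batch loss by the pair count", {
  box <- open_box(128, seed = 2)
  # single full batch: the first epoch's loss is evaluated before any update
  f_sum <- nn_mmds(box$X, 2, epochs = 2, batch_size = 128, seed = 4)
  f_avg <- nn_mmds(box$X, 2, epochs = 2, batch_size = 128, seed = 4,
                   average_loss = TRUE)
  expect_equal(f_sum$loss_trace[1] / f_avg$loss_trace[1], choose(128, 2))
})

test_that("random initialization remains available and seeded", {
  box <- open_box(100, seed = 3)
  f1 <- nn_mmds(box$X, 2, epochs = 5, batch_size = 50, seed = 9, init = "random")
  f2 <- nn_mmds(box$X, 2, epochs = 5, batch_size = 50, seed = 9, init = "random")
  expect_identical(f1$embedding, f2$embedding)
  f3 <- nn_mmds(box$X, 2, epochs = 5, batch_size = 50, seed = 9)
  expect_false(identical(f1$embedding, f3$embedding))
})
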
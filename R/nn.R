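#' Initialize the two-layer embedding network
#'
#' Weights are drawn from the symmetric scaled-uniform (Glorot) scheme,
#' \eqn{W \sim U(-\sqrt{6/(fan_{in}+fan_{out})}, +\sqrt{6/(fan_{in}+fan_{out})})},
#' biases start at zero. Identical seeds yield identical weights.
#'
#' @param m input dimension (number of features).
#' @param h hidden-layer width.
#' @param k output (embedding) dimension.
#' @param seed RNG seed.
#' @return a list with `W1` (m x h), `b1` (h), `W2` (h x k), `b2` (k) and the
#'   dimensions.
#' @export
init_network <- function(m, h, k, seed = 1L) {
  if (any(c(m, h, k) < 1L)) stop("dimensions must be positive", call. = FALSE)
  with_seed(seed, init_weights(m, h, k))
}

init_weights <- function(m, h, k) {
  lim1 <- sqrt(6 / (m + h))
  lim2 <- sqrt(6 / (h + k))
  list(
    W1 = matrix(stats::runif(m * h, -lim1, lim1), m, h),
    b1 = numeric(h),
    W2 = matrix(stats::runif(h * k, -lim2, lim2), h, k),
    b2 = numeric(k),
    m = as.integer(m), h = as.integer(h), k = as.integer(k)
  )
}

# PCA-aligned initialization: hidden unit j computes tanh(a_j <x - mu, v_j>)
# with gain a_j placing the pre-activation RMS at ~0.5 (tanh near-linear),
# and the output layer undoes the gain on the first k units so the initial
# embedding approximates the PCA scores. Hidden units beyond the rank, and
# all output weights, receive small seeded scaled-uniform noise so gradient
# descent can recruit them.
spectral_init_weights <- function(Xt, h, k) {
  n <- nrow(Xt); m <- ncol(Xt)
  mu <- colMeans(Xt)
  sv <- svd(sweep(Xt, 2L, mu, "-"), nu = 0L, nv = min(h, m))
  params <- init_weights(m, h, k)
  params$W1 <- params$W1 * 0.01
  params$W2 <- params$W2 * 0.01
  target_rms <- 0.5
  r <- sum(sv$d > sv$d[1L] * 1e-10)
  for (j in seq_len(min(h, r))) {
    gain <- target_rms * sqrt(n) / sv$d[j]
    params$W1[, j] <- gain * sv$v[, j]
    if (j <= k) params$W2[j, j] <- 1 / gain
  }
  params$b1 <- -as.numeric(mu %*% params$W1)
  params
}

nn_forward <- function(params, X) {
  H <- tanh(sweep(X %*% params$W1, 2L, params$b1, "+"))
  Y <- sweep(H %*% params$W2, 2L, params$b2, "+")
  list(H = H, Y = Y)
}

# Full b x b distance matrix within a batch (never a precomputed n x n one).
batch_distances <- function(Xb, metric) {
  if (metric == "euclidean") {
    as.matrix(stats::dist(Xb))
  } else {
    pairwise_distances(Xb, metric, max_n = Inf)
  }
}

#' Siamese pair loss of a batch
#'
#' Sum over all unordered pairs (i < j) within the batch of the squared
#' difference between the input-space distance of the two points and the
#' Euclidean distance of their embeddings:
#' \deqn{\sum_{i<j} (d(x_i, x_j) - \|y_i - y_j\|)^2.}
#' Output-space distance is always Euclidean regardless of `metric`.
#'
#' @param X_batch b x m matrix of input points (b >= 2).
#' @param Y_batch b x k matrix of their embeddings, rows aligned.
#' @param metric input-space metric.
#' @return a single nonnegative number.
#' @export
batch_pair_loss <- function(X_batch, Y_batch, metric = "euclidean") {
  X_batch <- as_dense_matrix(X_batch, "X_batch")
  Y_batch <- as_dense_matrix(Y_batch, "Y_batch")
  if (nrow(X_batch) < 2L) stop("batch must contain at least 2 points", call. = FALSE)
  if (nrow(X_batch) != nrow(Y_batch)) {
    stop("`X_batch` and `Y_batch` must have the same number of rows", call. = FALSE)
  }
  DX <- batch_distances(X_batch, metric)
  DY <- as.matrix(stats::dist(Y_batch))
  sum((DX - DY)^2) / 2
}

#' Fit a neural metric-MDS embedding
#'
#' Trains a fully-connected network with a single tanh hidden layer and a
#' linear output layer to minimize the pairwise-distance stress. Each epoch
#' the rows are shuffled and partitioned into minibatches; within a batch the
#' loss is the sum over all unordered point pairs of the squared difference
#' between input-space distance and embedded Euclidean distance, and the
#' weights are updated with the Adam optimizer. Input-space distances are
#' computed on the fly per batch, so no dense n x n matrix is ever formed --
#' this is what lets the method scale.
#'
#' The hidden width defaults to `"auto"`: the SVD-based
#' [intrinsic_dimension()] of the data at the 95% variance threshold, raised
#' to `k` if smaller (a bottleneck narrower than the output is never useful).
#'
#' For the Euclidean metric the input is divided by its root-mean-square
#' pairwise distance (computed in closed form from the centered Frobenius
#' norm) and the network output is multiplied by the same factor in the
#' forward map. This is an exact reparameterization of the objective -- both
#' input and output distances scale linearly -- that keeps weights,
#' activations and Adam steps at unit scale regardless of the units of the
#' data. The factor is stored in the model so [predict.nn_mmds()] applies the
#' identical map. Cosine and correlation distances are scale-free already and
#' are left untouched.
#'
#' A single RNG stream derived from `seed` drives the weight initialization
#' and every epoch's shuffle, so identical inputs and configuration reproduce
#' the embedding exactly.
#'
#' @param X numeric observation-by-feature matrix, n >= 2 finite rows.
#' @param k target embedding dimension.
#' @param epochs number of passes over the data (default 1000).
#' @param batch_size minibatch size (default 256; at least 2). A trailing
#'   singleton batch is merged into its predecessor.
#' @param learning_rate Adam step size (default 1e-3).
#' @param metric input-space metric: `"euclidean"`, `"cosine"` or
#'   `"correlation"`.
#' @param hidden `"auto"` or a positive integer hidden width.
#' @param init `"spectral"` (default) aligns the hidden layer with the top
#'   right-singular vectors of the data, scaled into the linear range of
#'   tanh, and sets the output layer to reproduce the PCA scores, so
#'   training starts from the classical-MDS configuration (the same start
#'   SMACOF's classical initialization and the projected-mMDS solver use)
#'   and refines it nonlinearly; `"random"` uses the scaled-uniform scheme
#'   of [init_network()]. The spectral start makes the final stress far less
#'   dependent on the seed.
#' @param standardize if `TRUE`, features are centered and scaled before
#'   training; the fitted state is stored so [predict.nn_mmds()] applies the
#'   identical transformation.
#' @param average_loss if `TRUE` the per-batch loss (and gradient) is averaged
#'   over pairs instead of summed; this only rescales the gradient.
#' @param seed RNG seed.
#' @param verbose print the epoch loss every 50 epochs.
#' @return an object of class `"nn_mmds"` with components `embedding`
#'   (n x k), `loss_trace` (mean per-batch loss per epoch), `model`
#'   (weights, dims, preprocessing state) and `config`.
#' @seealso [predict.nn_mmds()], [write_nn_model()]
#' @export
nn_mmds <- function(X, k, epochs = 1000L, batch_size = 256L,
                    learning_rate = 1e-3,
                    metric = c("euclidean", "cosine", "correlation"),
                    hidden = "auto", init = c("spectral", "random"),
                    standardize = FALSE,
                    average_loss = FALSE, seed = 1L, verbose = FALSE) {
  metric <- match.arg(metric)
  init <- match.arg(init)
  X <- as_dense_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (batch_size < 2L) stop("`batch_size` must be at least 2", call. = FALSE)
  if (k < 1L) stop("`k` must be positive", call. = FALSE)

  if (identical(hidden, "auto")) {
    h <- max(intrinsic_dimension(X), as.integer(k))
  } else {
    h <- as.integer(hidden)
    if (is.na(h) || h < 1L) stop("`hidden` must be \"auto\" or a positive integer", call. = FALSE)
  }

  center <- NULL; scale_ <- NULL
  Xt <- X
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
    Xt <- sweep(sweep(X, 2L, center, "-"), 2L, scale_, "/")
  }

  # conditioning: unit RMS pairwise distance (Euclidean only; exact
  # reparameterization, undone on the output side of the forward map)
  dist_scale <- 1
  if (metric == "euclidean") {
    Xc <- sweep(Xt, 2L, colMeans(Xt), "-")
    rms <- sqrt(2 * sum(Xc^2) / n)  # ||D_X||_F / n for centered rows
    if (rms > 0) dist_scale <- rms
    Xt <- Xt / dist_scale
  }

  res <- with_seed(seed, {
    params <- if (init == "spectral") {
      spectral_init_weights(Xt, h, k)
    } else {
      init_weights(m, h, k)
    }
    opt <- adam_state(params)
    loss_trace <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      batches <- lapply(starts, function(s) perm[s:min(s + batch_size - 1L, n)])
      if (length(batches) > 1L && length(batches[[length(batches)]]) == 1L) {
        nb <- length(batches)
        batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      batch_losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        Xb <- Xt[idx, , drop = FALSE]
        fw <- nn_forward(params, Xb)
        DXb <- batch_distances(Xb, metric)
        DY <- as.matrix(stats::dist(fw$Y))
        diff <- DY - DXb
        loss <- sum(diff^2) / 2
        npairs <- length(idx) * (length(idx) - 1) / 2
        if (average_loss) loss <- loss / npairs
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d; try a smaller learning rate",
                       epoch), call. = FALSE)
        }
        batch_losses[bi] <- loss
        # dL/dY: A_ij = 2 (DY - DX)_ij / DY_ij (0 where DY = 0)
        A <- 2 * diff / DY
        A[DY == 0] <- 0
        gY <- rowSums(A) * fw$Y - A %*% fw$Y
        if (average_loss) gY <- gY / npairs
        grads <- nn_backward(params, Xb, fw$H, gY)
        opt <- adam_step(params, grads, opt, learning_rate)
        params <- opt$params
      }
      loss_trace[epoch] <- mean(batch_losses)
      if (verbose && (epoch %% 50L == 0L || epoch == 1L)) {
        message(sprintf("epoch %d: mean batch loss %.6g", epoch, loss_trace[epoch]))
      }
    }
    list(params = params, loss_trace = loss_trace)
  })

  model <- c(res$params,
             list(metric = metric, standardize = standardize,
                  center = center, scale = scale_, dist_scale = dist_scale,
                  seed = as.integer(seed)))
  embedding <- dist_scale * nn_forward(res$params, Xt)$Y
  rownames(embedding) <- rownames(X)
  structure(
    list(embedding = embedding,
         loss_trace = res$loss_trace * dist_scale^2,
         model = model,
         config = list(k = as.integer(k), epochs = as.integer(epochs),
                       batch_size = as.integer(batch_size),
                       learning_rate = learning_rate, metric = metric,
                       hidden = h, init = init, standardize = standardize,
                       average_loss = average_loss, seed = as.integer(seed))),
    class = "nn_mmds")
}

nn_backward <- function(params, Xb, H, gY) {
  gW2 <- crossprod(H, gY)
  gb2 <- colSums(gY)
  gH <- tcrossprod(gY, params$W2) * (1 - H^2)
  gW1 <- crossprod(Xb, gH)
  gb1 <- colSums(gH)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_state <- function(params) {
  zeros <- lapply(params[c("W1", "b1", "W2", "b2")], function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L, params = params)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in c("W1", "b1", "W2", "b2")) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  opt$params <- params
  opt
}

#' Map new observations through a fitted neural embedding
#'
#' A pure forward pass through the stored weights, applying the stored
#' feature standardization first if the model was fitted with it. No
#' retraining occurs; applying it to the training matrix reproduces the
#' training embedding exactly.
#'
#' @param object an `"nn_mmds"` fit.
#' @param newdata matrix with the same number of columns as the training data.
#' @param ... ignored.
#' @return an n_new x k embedding matrix.
#' @export
predict.nn_mmds <- function(object, newdata, ...) {
  X <- as_dense_matrix(newdata, "newdata")
  model <- object$model
  if (ncol(X) != model$m) {
    stop(sprintf("`newdata` has %d columns but the model expects %d",
                 ncol(X), model$m), call. = FALSE)
  }
  if (isTRUE(model$standardize)) {
    X <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  }
  ds <- model$dist_scale %||% 1
  Y <- ds * nn_forward(model, X / ds)$Y
  rownames(Y) <- rownames(newdata)
  Y
}

#' @export
print.nn_mmds <- function(x, ...) {
  cat(sprintf("Neural metric-MDS embedding: %d points, %d -> %d (hidden %d)\n",
              nrow(x$embedding), x$model$m, x$model$k, x$model$h))
  cat(sprintf("  metric: %s | epochs: %d | final mean batch loss: %.6g\n",
              x$config$metric, x$config$epochs,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}
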
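#' Open-box surface sampler
#'
#' Samples points uniformly on the five faces of an axis-aligned cube with
#' the top face removed -- a lidless 3-D box. A linear map cannot unfold
#' this surface into the plane, while a nonlinear distance-preserving map
#' can, which makes it the canonical fixture for comparing the neural
#' embedding against PCA, random projection and projected metric MDS.
#'
#' Faces all have area `side^2`, so the face of each point is drawn
#' uniformly from the five faces (area-weighted sampling); coordinates
#' within a face are uniform. Labels are the face index: 0 bottom (z = 0),
#' 1..4 the four walls.
#'
#' @param n number of points (at least 5).
#' @param side edge length of the cube (default 1).
#' @param seed RNG seed; same seed, same data.
#' @return a list of class `"labeled_dataset"` with `X` (n x 3 matrix),
#'   `labels` (integer face indices) and `params`.
#' @export
open_box <- function(n, side = 1, seed = 1L) {
  if (n < 5L) stop("`n` must be at least 5", call. = FALSE)
  if (side <= 0) stop("`side` must be positive", call. = FALSE)
  with_seed(seed, {
    face <- sample.int(5L, n, replace = TRUE) - 1L
    u <- stats::runif(n, 0, side)
    v <- stats::runif(n, 0, side)
    X <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
    bottom <- face == 0L
    X[bottom, ] <- cbind(u[bottom], v[bottom], 0)
    w1 <- face == 1L  # y = 0 wall
    X[w1, ] <- cbind(u[w1], 0, v[w1])
    w2 <- face == 2L  # y = side wall
    X[w2, ] <- cbind(u[w2], side, v[w2])
    w3 <- face == 3L  # x = 0 wall
    X[w3, ] <- cbind(0, u[w3], v[w3])
    w4 <- face == 4L  # x = side wall
    X[w4, ] <- cbind(side, u[w4], v[w4])
    structure(list(X = X, labels = face,
                   params = list(generator = "open_box", n = n, side = side,
                                 seed = as.integer(seed))),
              class = "labeled_dataset")
  })
}

#' Well-separated isotropic Gaussian clusters
#'
#' Draws `n_clusters` isotropic unit-variance Gaussian blobs in m
#' dimensions with centers at pairwise distance at least `separation`
#' (centers are drawn at random and rescaled if any pair falls short).
#' Cluster sizes are balanced up to the remainder.
#'
#' @param n total number of points (at least `n_clusters`).
#' @param m feature dimension (default 10).
#' @param n_clusters number of clusters.
#' @param separation minimum pairwise distance between cluster centers
#'   (default 10).
#' @param seed RNG seed.
#' @return a `"labeled_dataset"` with `X` (n x m), `labels` in
#'   `0:(n_clusters-1)` and `params`.
#' @export
gaussian_clusters <- function(n, m = 10L, n_clusters = 3L, separation = 10,
                              seed = 1L) {
  if (n_clusters < 1L) stop("`n_clusters` must be at least 1", call. = FALSE)
  if (n < n_clusters) stop("`n` must be at least `n_clusters`", call. = FALSE)
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_clusters * m, sd = max(separation, 1)),
                      n_clusters, m)
    if (n_clusters > 1L) {
      dmin <- min(stats::dist(centers))
      if (dmin < separation) centers <- centers * (separation / dmin)
    }
    sizes <- rep(n %/% n_clusters, n_clusters)
    rem <- n - sum(sizes)
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    labels <- rep(seq_len(n_clusters) - 1L, sizes)
    X <- centers[labels + 1L, , drop = FALSE] + matrix(stats::rnorm(n * m), n, m)
    structure(list(X = X, labels = labels, centers = centers,
                   params = list(generator = "gaussian_clusters", n = n, m = m,
                                 n_clusters = n_clusters,
                                 separation = separation,
                                 seed = as.integer(seed))),
              class = "labeled_dataset")
  })
}

#' Synthetic sparse scRNA-seq-like count matrix
#'
#' Emulates the gross statistical shape of a droplet scRNA-seq count matrix:
#' log-normal gene expression programs with cluster-specific up-regulated
#' marker blocks, log-normal cell size factors, and Poisson sampling thinned
#' so the matrix is mostly zeros (>= 80% at the defaults). This is a
#' synthetic stand-in for testing pipelines end to end; it does not model
#' batch effects, dropouts beyond Poisson zeros, or realistic gene-gene
#' correlation.
#'
#' @param n_cells number of cells (rows; default 500).
#' @param n_genes number of genes (columns; default 1000).
#' @param n_clusters number of cell populations (default 3).
#' @param mean_count target mean count per entry controlling sparsity
#'   (default 0.15, about 86% zeros).
#' @param seed RNG seed.
#' @return a `"labeled_dataset"` whose `X` is a sparse `dgCMatrix`
#'   (cells x genes) of nonnegative integer counts, writable as Matrix
#'   Market via [write_matrix()].
#' @export
scrna_like_counts <- function(n_cells = 500L, n_genes = 1000L,
                              n_clusters = 3L, mean_count = 0.15, seed = 1L) {
  if (n_clusters < 1L) stop("`n_clusters` must be at least 1", call. = FALSE)
  if (n_cells < n_clusters) stop("`n_cells` must be at least `n_clusters`", call. = FALSE)
  with_seed(seed, {
    # baseline gene program, shared across clusters
    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    # each cluster up-regulates its own block of marker genes 8-fold
    n_marker <- max(1L, n_genes %/% (4L * n_clusters))
    programs <- matrix(rep(base, n_clusters), n_clusters, n_genes, byrow = TRUE)
    for (cl in seq_len(n_clusters)) {
      idx <- ((cl - 1L) * n_marker + 1L):(cl * n_marker)
      idx <- idx[idx <= n_genes]
      programs[cl, idx] <- programs[cl, idx] * 8
    }
    programs <- programs / rowMeans(programs) * mean_count
    sizes <- rep(n_cells %/% n_clusters, n_clusters)
    rem <- n_cells - sum(sizes)
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    labels <- rep(seq_len(n_clusters) - 1L, sizes)
    size_factor <- stats::rlnorm(n_cells, meanlog = 0, sdlog = 0.3)
    mu <- programs[labels + 1L, , drop = FALSE] * size_factor
    counts <- matrix(stats::rpois(n_cells * n_genes, lambda = mu),
                     n_cells, n_genes)
    X <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    rownames(X) <- sprintf("cell%d", seq_len(n_cells))
    colnames(X) <- sprintf("gene%d", seq_len(n_genes))
    structure(list(X = X, labels = labels,
                   params = list(generator = "scrna_like_counts",
                                 n_cells = n_cells, n_genes = n_genes,
                                 n_clusters = n_clusters,
                                 mean_count = mean_count,
                                 seed = as.integer(seed))),
              class = "labeled_dataset")
  })
}

#' @export
print.labeled_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic dataset '%s': %d x %d, %d label level(s), seed %d\n",
              p$generator, nrow(x$X), ncol(x$X),
              length(unique(x$labels)), p$seed))
  invisible(x)
}
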
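# Portable model container: versioned JSON, numbers at 17 significant
# digits so a save/load round trip reproduces predictions bit-for-bit.

MODEL_FORMAT <- "mmdsnet-model"
MODEL_VERSION <- "1.0"

#' Save a fitted embedding model to a portable JSON container
#'
#' Stores dimensions, weights, biases, preprocessing state, configuration
#' and seed. Numeric values are written with full double precision, so a
#' round trip through [read_nn_model()] reproduces [predict.nn_mmds()]
#' output bit-for-bit. The container is versioned; loaders refuse files
#' written by a newer major version.
#'
#' Linear models (PCA loadings, random projections, projected metric MDS)
#' are saved through the same container with `type = "linear"`.
#'
#' @param object an `"nn_mmds"` fit, or a list with `P`/`loadings`(`projection`)
#'   and optionally `center` for linear maps.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_nn_model <- function(object, path) {
  if (inherits(object, "nn_mmds")) {
    m <- object$model
    payload <- list(
      format = MODEL_FORMAT, version = MODEL_VERSION, type = "nn",
      m = m$m, h = m$h, k = m$k,
      W1 = m$W1, b1 = m$b1, W2 = m$W2, b2 = m$b2,
      metric = m$metric, standardize = m$standardize,
      center = m$center, scale = m$scale,
      dist_scale = m$dist_scale %||% 1,
      seed = m$seed, config = object$config)
  } else {
    P <- object$P %||% object$loadings %||% object$projection
    if (is.null(P)) stop("no linear map found in `object`", call. = FALSE)
    payload <- list(
      format = MODEL_FORMAT, version = MODEL_VERSION, type = "linear",
      m = nrow(P), k = ncol(P), P = P,
      center = object$center)
  }
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load an embedding model saved by [write_nn_model()]
#'
#' @param path path to the JSON container.
#' @return for `type = "nn"`, an object of class `"nn_mmds"` usable with
#'   [predict.nn_mmds()]; for `type = "linear"`, a list of class
#'   `"linear_map"` with `P` and `center`, usable with [predict.linear_map()].
#' @export
read_nn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop(sprintf("%s: not a %s file", path, MODEL_FORMAT), call. = FALSE)
  }
  major <- as.integer(strsplit(obj$version, ".", fixed = TRUE)[[1L]][1L])
  have <- as.integer(strsplit(MODEL_VERSION, ".", fixed = TRUE)[[1L]][1L])
  if (is.na(major) || major > have) {
    stop(sprintf("%s: model version %s is newer than supported (%s)",
                 path, obj$version, MODEL_VERSION), call. = FALSE)
  }
  if (identical(obj$type, "linear")) {
    P <- matrix(as.numeric(obj$P), obj$m, obj$k, byrow = FALSE)
    # jsonlite returns a matrix already when rectangular
    if (is.matrix(obj$P)) P <- obj$P
    return(structure(list(P = P, center = obj$center), class = "linear_map"))
  }
  model <- list(
    W1 = matrix(obj$W1, obj$m, obj$h), b1 = as.numeric(obj$b1),
    W2 = matrix(obj$W2, obj$h, obj$k), b2 = as.numeric(obj$b2),
    m = obj$m, h = obj$h, k = obj$k,
    metric = obj$metric, standardize = isTRUE(obj$standardize),
    center = if (is.null(obj$center)) NULL else as.numeric(obj$center),
    scale = if (is.null(obj$scale)) NULL else as.numeric(obj$scale),
    dist_scale = obj$dist_scale %||% 1,
    seed = obj$seed)
  if (is.matrix(obj$W1)) model$W1 <- obj$W1
  if (is.matrix(obj$W2)) model$W2 <- obj$W2
  structure(list(model = model, config = obj$config), class = "nn_mmds")
}

#' Apply a saved linear map to new observations
#'
#' @param object a `"linear_map"` from [read_nn_model()].
#' @param newdata matrix with matching feature count.
#' @param ... ignored.
#' @return the mapped n x k matrix.
#' @export
predict.linear_map <- function(object, newdata, ...) {
  X <- as_dense_matrix(newdata, "newdata")
  if (ncol(X) != nrow(object$P)) {
    stop("`newdata` has the wrong number of columns", call. = FALSE)
  }
  if (!is.null(object$center)) X <- sweep(X, 2L, as.numeric(object$center), "-")
  X %*% object$P
}

`%||%` <- function(a, b) if (is.null(a)) b else a
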
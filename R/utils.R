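# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Coerce to a plain dense numeric matrix, keeping dimnames.
as_dense_matrix <- function(X, arg = "X") {
  if (inherits(X, "Matrix")) X <- as.matrix(X)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L || ncol(X) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg),
         call. = FALSE)
  }
  if (!all(is.finite(X))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  X
}

check_square_symmetric <- function(D, arg = "D", tol = 1e-8) {
  D <- as_dense_matrix(D, arg)
  if (nrow(D) != ncol(D)) {
    stop(sprintf("`%s` must be square", arg), call. = FALSE)
  }
  scale <- max(abs(D), 1)
  if (max(abs(D - t(D))) > tol * scale) {
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  }
  D
}
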
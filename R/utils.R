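# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# One-hot encode integer labels 1..p into an N x p 0/1 matrix.
one_hot <- function(y, p) {
  y <- as.integer(y)
  if (length(y) && (anyNA(y) || any(y < 1L) || any(y > p))) {
    stop("labels must be integers in 1..", p, call. = FALSE)
  }
  out <- matrix(0, nrow = length(y), ncol = p)
  if (length(y)) out[cbind(seq_along(y), y)] <- 1
  out
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (!is.numeric(X)) stop("feature matrix must be numeric", call. = FALSE)
  storage.mode(X) <- "double"
  X
}

check_labels <- function(y, n = NULL) {
  if (!is.numeric(y)) stop("labels must be numeric class codes", call. = FALSE)
  if (anyNA(y)) stop("labels contain missing values", call. = FALSE)
  if (any(y != round(y))) stop("labels must be integral class codes", call. = FALSE)
  if (!is.null(n) && length(y) != n) {
    stop("length of labels does not match number of rows", call. = FALSE)
  }
  as.integer(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
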
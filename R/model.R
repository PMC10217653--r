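# T2-FNN model object: antecedent grids (n_rules x m), consequent weights and
# type-reduction coefficients, plus optional scaler state carried along so a
# saved model can be applied to unscaled data.

new_it2fnn <- function(c1, c2, sigma, V, W, p_coef = 0.5, q_coef = 0.5,
                       tnorm = c("prod", "min"), scaler = NULL) {
  tnorm <- match.arg(tnorm)
  c1 <- as.matrix(c1); c2 <- as.matrix(c2); sigma <- as.matrix(sigma)
  V <- as.matrix(V); W <- as.matrix(W)
  n <- nrow(c1); m <- ncol(c1)
  model <- structure(
    list(m = m, n_rules = n, n_out = ncol(W),
         c1 = c1, c2 = c2, sigma = sigma, V = V, W = W,
         p_coef = p_coef, q_coef = q_coef, tnorm = tnorm, scaler = scaler),
    class = "it2fnn")
  validate_it2fnn(model)
}

validate_it2fnn <- function(model) {
  with(model, {
    if (!all(dim(c2) == c(n_rules, m)) || !all(dim(sigma) == c(n_rules, m))) {
      stop("antecedent grids must all be n_rules x m", call. = FALSE)
    }
    if (!all(dim(V) == c(m, n_rules))) stop("V must be m x n_rules", call. = FALSE)
    if (!all(dim(W) == c(n_rules, n_out))) stop("W must be n_rules x p", call. = FALSE)
    if (any(sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
    if (any(c1 > c2)) stop("all centers must satisfy c1 <= c2", call. = FALSE)
    if (abs(p_coef + q_coef - 1) > 1e-8) {
      stop("p_coef + q_coef must equal 1", call. = FALSE)
    }
  })
  model
}

#' Randomly initialize a T2-FNN model
#'
#' Draws antecedent centers uniformly on the scaled-data range \eqn{[0,1]}
#' with an uncertain-mean half-width \eqn{h \sim U(0.01, 0.1)} (so
#' \eqn{c_1 = c - h}, \eqn{c_2 = c + h}), widths \eqn{\sigma \sim U(0.05, 0.5)},
#' and consequent weights \eqn{V, W \sim U(-0.5, 0.5)}. Reproducible from
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param m Number of inputs.
#' @param n_rules Number of fuzzy rules.
#' @param n_out Number of outputs (classes).
#' @param seed Integer seed.
#' @param tnorm Conjunction operator for rule firing, `"prod"` (default) or
#'   `"min"`.
#' @return An `it2fnn` model with `p_coef = q_coef = 0.5`.
#' @examples
#' model <- it2fnn_init(m = 2, n_rules = 3, n_out = 2, seed = 1)
#' it2fnn_forward(model, c(0.2, 0.8))
#' @export
it2fnn_init <- function(m, n_rules, n_out, seed = 1L, tnorm = c("prod", "min")) {
  tnorm <- match.arg(tnorm)
  if (m < 1 || n_rules < 1 || n_out < 1) {
    stop("m, n_rules and n_out must all be >= 1", call. = FALSE)
  }
  with_seed(seed, {
    centers <- matrix(runif(n_rules * m), n_rules, m)
    half <- matrix(runif(n_rules * m, 0.01, 0.1), n_rules, m)
    sigma <- matrix(runif(n_rules * m, 0.05, 0.5), n_rules, m)
    V <- matrix(runif(m * n_rules, -0.5, 0.5), m, n_rules)
    W <- matrix(runif(n_rules * n_out, -0.5, 0.5), n_rules, n_out)
    new_it2fnn(centers - half, centers + half, sigma, V, W, tnorm = tnorm)
  })
}

#' Forward inference for a single input vector
#'
#' Composes [rule_firing()], [local_linear_outputs()] and
#' [type_reduced_output()] into the crisp output vector of the network.
#' Inputs are expected on the model's training scale (usually \eqn{[0,1]}).
#'
#' @param model An `it2fnn` model.
#' @param x Numeric input vector of length `model$m`.
#' @return Numeric vector of `model$n_out` crisp scores.
#' @export
it2fnn_forward <- function(model, x) {
  stopifnot(inherits(model, "it2fnn"))
  f <- rule_firing(x, model)
  y <- local_linear_outputs(x, model$V)
  type_reduced_output(f, y, model$W, model$p_coef, model$q_coef)
}

# Batch forward through the compiled core; returns N x p score matrix.
forward_scores <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != model$m) {
    stop("newdata has ", ncol(X), " columns but model expects ", model$m,
         call. = FALSE)
  }
  cpp_forward_batch(model$c1, model$c2, model$sigma, model$V, model$W,
                    model$p_coef, model$q_coef, X,
                    identical(model$tnorm, "min"))
}

#' Predict class labels or crisp scores
#'
#' Class decisions take the argmax of the crisp output vector (the model is
#' trained against one-hot targets); ties break toward the lowest class index.
#'
#' @param object An `it2fnn` model.
#' @param newdata Feature matrix or data frame (`N x m`), on the model's
#'   training scale.
#' @param type `"class"` for integer labels in `1..p`, `"score"` for the
#'   `N x p` matrix of crisp outputs.
#' @param ... Unused.
#' @return Integer label vector or score matrix.
#' @export
predict.it2fnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  U <- forward_scores(object, newdata)
  if (type == "score") return(U)
  if (nrow(U) == 0L) return(integer(0))
  apply(U, 1L, which.max)  # which.max ties break to the lowest index
}

#' @export
print.it2fnn <- function(x, ...) {
  cat("Interval type-2 fuzzy neural network\n")
  cat(sprintf("  inputs: %d   rules: %d   outputs: %d   t-norm: %s\n",
              x$m, x$n_rules, x$n_out, x$tnorm))
  cat(sprintf("  type-reduction blend: p = %.3f, q = %.3f\n", x$p_coef, x$q_coef))
  if (!is.null(x$scaler)) cat("  carries min-max scaler state\n")
  invisible(x)
}
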
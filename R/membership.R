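#' Interval type-2 Gaussian membership function with uncertain mean
#'
#' Constructs a Gaussian membership function whose center is only known to lie
#' in the interval \eqn{[c_1, c_2]}. The footprint of uncertainty is bounded
#' below and above by the membership envelopes returned by
#' [membership_interval()].
#'
#' @param c1 Lower bound of the uncertain center (scaled feature units).
#' @param c2 Upper bound of the uncertain center; must satisfy `c1 <= c2`.
#' @param sigma Width of the Gaussian; must be strictly positive. Note the
#'   membership exponent is \eqn{-(x-c)^2/\sigma^2} (no factor 2).
#' @return An object of class `it2_gaussian`.
#' @examples
#' mf <- it2_gaussian(0.4, 0.6, 0.2)
#' membership_interval(0.5, mf)
#' @export
it2_gaussian <- function(c1, c2, sigma) {
  stopifnot(is.numeric(c1), is.numeric(c2), is.numeric(sigma),
            length(c1) == 1L, length(c2) == 1L, length(sigma) == 1L)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a strictly positive width", call. = FALSE)
  }
  if (c1 > c2) stop("c1 must not exceed c2", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, sigma = sigma), class = "it2_gaussian")
}

#' Lower and upper membership grades of an interval type-2 Gaussian
#'
#' Evaluates the uncertain-mean construction: the upper membership is 1 on the
#' center interval \eqn{[c_1, c_2]} and decays as a Gaussian through the nearer
#' center outside it; the lower membership is the pointwise minimum of the two
#' center Gaussians \eqn{\exp(-(x-c_a)^2/\sigma^2)}.
#'
#' @param x Numeric vector of input values (scaled feature units).
#' @param mf An [it2_gaussian()] membership function.
#' @return A list with numeric vectors `lower` and `upper`, each in
#'   \eqn{[0, 1]} with `lower <= upper` elementwise.
#' @examples
#' membership_interval(c(0.2, 0.5, 0.9), it2_gaussian(0.4, 0.6, 0.2))
#' @export
membership_interval <- function(x, mf) {
  if (!inherits(mf, "it2_gaussian")) mf <- do.call(it2_gaussian, as.list(mf))
  if (!is.finite(mf$sigma) || mf$sigma <= 0) {
    stop("sigma must be a strictly positive width", call. = FALSE)
  }
  s2 <- mf$sigma^2
  g1 <- exp(-(x - mf$c1)^2 / s2)
  g2 <- exp(-(x - mf$c2)^2 / s2)
  lower <- pmin(g1, g2)
  upper <- ifelse(x < mf$c1, g1, ifelse(x > mf$c2, g2, 1))
  list(lower = lower, upper = upper)
}

#' Interval firing strengths of all rules for one input vector
#'
#' Conjoins the per-input membership intervals of each rule with the product
#' t-norm (the default, matching the printed rule-strength formula) or with
#' minimum, yielding the rule's lower and upper firing strengths.
#'
#' @param x Numeric input vector of length `m`.
#' @param model An `it2fnn` model (see [it2fnn_init()]).
#' @return A list with `lower` and `upper`, non-negative vectors of length
#'   `n_rules` with `lower <= upper <= 1` elementwise.
#' @export
rule_firing <- function(x, model) {
  stopifnot(inherits(model, "it2fnn"))
  if (length(x) != model$m) {
    stop("input has length ", length(x), " but model expects ", model$m,
         call. = FALSE)
  }
  s2 <- model$sigma^2
  xr <- matrix(x, nrow = model$n_rules, ncol = model$m, byrow = TRUE)
  g1 <- exp(-(xr - model$c1)^2 / s2)
  g2 <- exp(-(xr - model$c2)^2 / s2)
  lo <- pmin(g1, g2)
  hi <- ifelse(xr < model$c1, g1, ifelse(xr > model$c2, g2, 1))
  if (identical(model$tnorm, "min")) {
    f_lower <- apply(lo, 1L, min)
    f_upper <- apply(hi, 1L, min)
  } else {
    f_lower <- apply(lo, 1L, prod)
    f_upper <- apply(hi, 1L, prod)
  }
  list(lower = as.numeric(f_lower), upper = as.numeric(f_upper))
}

#' Rule-local linear consequents
#'
#' Each rule carries a linear function of the inputs (no bias term):
#' \eqn{y_j = \sum_i x_i v_{ij}}.
#'
#' @param x Numeric input vector of length `m`.
#' @param V `m x n` matrix of consequent weights, one column per rule.
#' @return Numeric vector of the `n` rule outputs.
#' @export
local_linear_outputs <- function(x, V) {
  V <- as.matrix(V)
  if (length(x) != nrow(V)) {
    stop("input length ", length(x), " does not match nrow(V) = ", nrow(V),
         call. = FALSE)
  }
  as.numeric(crossprod(V, x))
}

#' Type reduction and defuzzification to crisp outputs
#'
#' Collapses the interval inference result with the closed-form blend
#' \deqn{u_k = p \frac{\sum_j \underline{f}_j y_j w_{jk}}{\sum_j \underline{f}_j}
#'       + q \frac{\sum_j \bar{f}_j y_j w_{jk}}{\sum_j \bar{f}_j}.}
#' The weighted means are scale-invariant in the firing strengths, so even
#' very small sums are used as-is; only a denominator that underflowed to
#' (numerically) zero is guarded, by adding 1e-12, with a diagnostic message.
#'
#' @param f Firing strengths as returned by [rule_firing()].
#' @param y Rule outputs from [local_linear_outputs()].
#' @param W `n x p` matrix of output weights.
#' @param p_coef,q_coef Blend coefficients for the lower and upper weighted
#'   means; `p_coef + q_coef` should equal 1 (0.5/0.5 by default elsewhere).
#' @return Numeric vector of the `p` crisp outputs.
#' @export
type_reduced_output <- function(f, y, W, p_coef = 0.5, q_coef = 0.5) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(length(f$lower) == n, length(f$upper) == n, length(y) == n)
  eps <- 1e-12
  s_lo <- sum(f$lower)
  s_hi <- sum(f$upper)
  if (s_lo <= 1e-300 || s_hi <= 1e-300) {
    # only a denominator that underflowed to ~0 is guarded: the weighted mean
    # itself is scale-invariant in the firing strengths, so tiny but
    # representable sums must be left untouched
    message("type_reduced_output: firing strengths underflowed; ",
            "epsilon guard applied to a type-reduction denominator")
    if (s_lo <= 1e-300) s_lo <- s_lo + eps
    if (s_hi <= 1e-300) s_hi <- s_hi + eps
  }
  num_lo <- as.numeric(crossprod(W, f$lower * y))
  num_hi <- as.numeric(crossprod(W, f$upper * y))
  p_coef * num_lo / s_lo + q_coef * num_hi / s_hi
}
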
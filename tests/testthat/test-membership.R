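# Interval type-2 membership evaluation and forward inference.

test_that("membership interval follows the uncertain-mean construction", {
  mf <- it2_gaussian(0.4, 0.6, 0.2)
  mu <- membership_interval(0.5, mf)
  expect_identical(mu$upper, 1)              # x inside the center interval
  expect_equal(mu$lower, exp(-0.25))         # min of the two center Gaussians

  # degenerate type-1 Gaussian at its own center
  mu <- membership_interval(0.3, it2_gaussian(0.3, 0.3, 0.1))
  expect_equal(mu$lower, 1)
  expect_equal(mu$upper, 1)

  # far tail: both bounds vanish
  mu <- membership_interval(1e3, mf)
  expect_lt(mu$upper, 1e-300)
  expect_lte(mu$lower, mu$upper)

  # upper equals 1 exactly on [c1, c2], Gaussian through the nearer center outside
  xs <- seq(-0.5, 1.5, by = 0.01)
  mu <- membership_interval(xs, mf)
  inside <- xs >= 0.4 & xs <= 0.6
  expect_true(all(mu$upper[inside] == 1))
  expect_true(all(mu$upper[xs < 0.39 | xs > 0.61] < 1))
  expect_true(all(mu$lower >= 0 & mu$lower <= mu$upper & mu$upper <= 1))
  left <- xs < 0.4
  expect_equal(mu$upper[left], exp(-(xs[left] - 0.4)^2 / 0.04))
})

test_that("invalid membership parameters are rejected", {
  expect_error(it2_gaussian(0.4, 0.6, 0), "sigma")
  expect_error(it2_gaussian(0.4, 0.6, -1), "sigma")
  expect_error(it2_gaussian(0.7, 0.6, 0.1), "c1")
})

test_that("rule firing conjoins per-input membership intervals", {
  # build a 2-input, 1-rule model whose memberships at x are known:
  # choose centers/widths so that input intervals are (0.5, 0.8) and (0.7, 0.9)
  solve_mf <- function(lo, hi, x = 0.5) {
    # upper = exp(-(x-c2)^2/s^2) with x > c2; lower via farther center c1
    s <- 0.2
    c2 <- x - s * sqrt(-log(hi))
    c1 <- x - s * sqrt(-log(lo))
    c(c1 = c1, c2 = c2, s = s)
  }
  a <- solve_mf(0.5, 0.8)
  b <- solve_mf(0.7, 0.9)
  model <- it2fnn_init(2, 1, 2, seed = 1)
  model$c1 <- matrix(c(a["c1"], b["c1"]), 1, 2)
  model$c2 <- matrix(c(a["c2"], b["c2"]), 1, 2)
  model$sigma <- matrix(0.2, 1, 2)
  f <- rule_firing(c(0.5, 0.5), model)
  expect_equal(f$lower, 0.5 * 0.7)
  expect_equal(f$upper, 0.8 * 0.9)

  # one input with zero membership annihilates the rule
  f0 <- rule_firing(c(1e6, 0.5), model)
  expect_equal(f0$lower, 0)
  expect_equal(f0$upper, 0)

  # m = 1: firing equals that input's membership interval
  m1 <- it2fnn_init(1, 1, 2, seed = 2)
  mu <- membership_interval(0.42, it2_gaussian(m1$c1[1, 1], m1$c2[1, 1],
                                               m1$sigma[1, 1]))
  f1 <- rule_firing(0.42, m1)
  expect_equal(f1$lower, mu$lower)
  expect_equal(f1$upper, mu$upper)

  expect_error(rule_firing(c(0.1, 0.2, 0.3), model), "length")
})

test_that("interval firing strengths are ordered and bounded", {
  model <- it2fnn_init(4, 6, 3, seed = 9)
  for (s in 1:20) {
    x <- with_seed_test(s, runif(4))
    f <- rule_firing(x, model)
    expect_true(all(f$lower >= 0))
    expect_true(all(f$lower <= f$upper))
    expect_true(all(f$upper <= 1))
  }
})

test_that("local linear consequents compute x' V per rule without bias", {
  V <- matrix(c(1, 2), nrow = 2, ncol = 1)
  expect_equal(local_linear_outputs(c(0.5, 0.25), V), 1.0)
  expect_equal(local_linear_outputs(c(0, 0), matrix(runif(6), 2, 3)),
               c(0, 0, 0))
  # selector column picks out one input
  V <- matrix(c(0, 1), 2, 1)
  expect_equal(local_linear_outputs(c(0.3, 0.8), V), 0.8)
  expect_error(local_linear_outputs(c(1, 2, 3), V), "match")
})

test_that("type reduction collapses correctly in degenerate cases", {
  # f_lower == f_upper: standard TSK weighted mean
  f <- list(lower = c(0.2, 0.5), upper = c(0.2, 0.5))
  y <- c(1, -2)
  W <- matrix(c(0.5, 1, -1, 0.25), 2, 2)
  u <- type_reduced_output(f, y, W)
  expect_equal(u, as.numeric(crossprod(W, f$lower * y)) / sum(f$lower))

  # single rule: denominators cancel, u_k = y_1 w_1k
  f1 <- list(lower = 0.37, upper = 0.9)
  u1 <- type_reduced_output(f1, 2, matrix(c(0.5, -1), 1, 2))
  expect_equal(u1, 2 * c(0.5, -1))

  # near-zero firing triggers the epsilon guard plus a diagnostic
  fz <- list(lower = c(0, 0), upper = c(0, 0))
  expect_message(uz <- type_reduced_output(fz, y, W), "guard")
  expect_true(all(is.finite(uz)))
})

test_that("forward output is invariant under consistent rule permutation", {
  model <- it2fnn_init(3, 5, 3, seed = 4)
  perm <- c(3, 5, 1, 2, 4)
  permuted <- model
  permuted$c1 <- model$c1[perm, , drop = FALSE]
  permuted$c2 <- model$c2[perm, , drop = FALSE]
  permuted$sigma <- model$sigma[perm, , drop = FALSE]
  permuted$V <- model$V[, perm, drop = FALSE]
  permuted$W <- model$W[perm, , drop = FALSE]
  for (s in 1:5) {
    x <- with_seed_test(s, runif(3))
    expect_equal(it2fnn_forward(permuted, x), it2fnn_forward(model, x),
                 tolerance = 1e-14)
  }
})

test_that("forward is deterministic and linear in the output weights", {
  model <- it2fnn_init(3, 4, 2, seed = 8)
  x <- c(0.2, 0.6, 0.9)
  expect_identical(it2fnn_forward(model, x), it2fnn_forward(model, x))
  doubled <- model
  doubled$W <- 2 * model$W
  expect_equal(it2fnn_forward(doubled, x), 2 * it2fnn_forward(model, x),
               tolerance = 1e-12)
})

test_that("R-level forward and the compiled batch forward agree", {
  for (s in 1:5) {
    model <- it2fnn_init(4, 6, 3, seed = s)
    X <- with_seed_test(100 + s, matrix(runif(20), 5, 4))
    U <- predict(model, X, type = "score")
    for (r in 1:5) {
      expect_equal(it2fnn_forward(model, X[r, ]), unname(U[r, ]),
                   tolerance = 1e-14)
    }
  }
  # and with the min t-norm variant
  model <- it2fnn_init(3, 4, 2, seed = 5, tnorm = "min")
  x <- c(0.1, 0.5, 0.9)
  expect_equal(it2fnn_forward(model, x),
               unname(predict(model, matrix(x, 1), type = "score")[1, ]),
               tolerance = 1e-14)
})

test_that("class prediction takes the argmax with ties to the lowest index", {
  model <- it2fnn_init(2, 3, 3, seed = 3)
  # craft scores via a one-rule model with known outputs
  one <- it2fnn_init(1, 1, 3, seed = 1)
  one$V <- matrix(1, 1, 1)
  one$W <- matrix(c(0.9, 0.1, 0.0), 1, 3)
  expect_identical(predict(one, matrix(1, 1, 1)), 1L)
  one$W <- matrix(c(0.5, 0.5, 0.1), 1, 3)
  expect_identical(predict(one, matrix(1, 1, 1)), 1L)  # tie -> lowest index
  expect_identical(predict(model, matrix(numeric(0), 0, 2)), integer(0))
})
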
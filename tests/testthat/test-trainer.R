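# Gradient-descent training machinery.

test_that("model initialization is reproducible and respects invariants", {
  a <- it2fnn_init(5, 7, 3, seed = 42)
  b <- it2fnn_init(5, 7, 3, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$c1 <= a$c2))
  expect_true(all(a$sigma > 0))
  expect_true(all(a$c2 - a$c1 >= 0.02 - 1e-12 & a$c2 - a$c1 <= 0.2 + 1e-12))
  c <- it2fnn_init(5, 7, 3, seed = 43)
  expect_false(identical(a$c1, c$c1))
  expect_error(it2fnn_init(0, 7, 3), ">= 1")
})

test_that("per-sample loss is the sum of squared output deviations", {
  expect_identical(sample_error(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_identical(sample_error(c(1, 0, 0), c(0, 1, 0)), 2)
  u <- c(0.2, -0.3); d <- c(0.5, 0.1)
  expect_equal(sample_error(u + 3 * (d - u), d), 4 * sample_error(u, d))
  expect_error(sample_error(c(1, 2), c(1, 2, 3)), "length")
})

test_that("analytic gradients match central finite differences", {
  set.seed(1)
  cases <- 8L
  for (s in seq_len(cases)) {
    m <- sample(2:5, 1); n <- sample(2:5, 1); p <- sample(2:3, 1)
    model <- it2fnn_init(m, n, p, seed = 1000 + s)
    x <- runif(m)
    u_d <- as.numeric(sample(c(0, 1), p, replace = TRUE))
    g <- it2fnn_gradients(model, x, u_d)
    expect_grad_close(g, fd_gradients(model, x, u_d))
  }
})

test_that("gradients vanish at a perfect fit and push W against the residual", {
  model <- it2fnn_init(2, 3, 2, seed = 7)
  x <- c(0.4, 0.6)
  u <- it2fnn_forward(model, x)
  g <- it2fnn_gradients(model, x, u)   # target == output
  for (nm in c("c1", "c2", "sigma", "V", "W")) {
    expect_equal(max(abs(g[[nm]])), 0)
  }
  # with positive firing and positive y_j, dE/dw_jk opposes the residual
  model$V <- abs(model$V)
  g <- it2fnn_gradients(model, c(0.4, 0.6), c(10, 10))  # large positive residual
  expect_true(all(g$W < 0))
})

test_that("momentum update repairs invariants and reduces to plain SGD", {
  model <- it2fnn_init(2, 3, 2, seed = 5)
  zero <- it2fnn_gradients(model, c(0.5, 0.5), it2fnn_forward(model, c(0.5, 0.5)))
  res <- update_parameters(model, zero, lr = 0.1, momentum = 0.9)
  expect_equal(res$model[c("c1", "c2", "sigma", "V", "W")],
               model[c("c1", "c2", "sigma", "V", "W")])

  grads <- list(c1 = model$c1 * 0 + 1, c2 = model$c2 * 0 - 1,
                sigma = model$sigma * 0, V = model$V * 0 + 2,
                W = model$W * 0 - 2)
  res <- update_parameters(model, grads, lr = 0.01, momentum = 0)
  expect_equal(res$model$V, model$V - 0.01 * 2)
  expect_equal(res$model$W, model$W + 0.01 * 2)

  # a step that inverts a center pair gets swapped back into order
  big <- list(c1 = model$c1 * 0 - 100, c2 = model$c2 * 0 + 100,
              sigma = model$sigma * 0 + 1e6, V = model$V * 0, W = model$W * 0)
  res <- update_parameters(model, big, lr = 1, momentum = 0)
  expect_true(all(res$model$c1 <= res$model$c2))
  expect_true(all(res$model$sigma >= 1e-4))
})

test_that("repeated single-sample updates drive the loss to zero on a one-rule toy", {
  model <- it2fnn_init(1, 1, 2, seed = 3)
  model$V <- matrix(0.5, 1, 1)
  model$W <- matrix(c(0.3, -0.2), 1, 2)
  x <- 1
  u_d <- c(0.8, -0.4)
  vel <- NULL
  E <- sample_error(it2fnn_forward(model, x), u_d)
  errors <- E
  for (it in 1:20000) {
    g <- it2fnn_gradients(model, x, u_d)
    res <- if (is.null(vel)) update_parameters(model, g, lr = 1e-3, momentum = 0)
           else update_parameters(model, g, lr = 1e-3, momentum = 0, vel)
    model <- res$model; vel <- res$velocity
    E <- sample_error(it2fnn_forward(model, x), u_d)
    errors <- c(errors, E)
    if (E < 1e-6) break
  }
  expect_lt(E, 1e-6)
  expect_true(all(diff(errors) < 0))
})

test_that("k-fold partition covers all indices with balanced disjoint folds", {
  f <- kfold_partition(100, 10, seed = 1)
  expect_length(f, 10)
  expect_true(all(lengths(f) == 10))
  expect_identical(sort(unlist(f)), 1:100)

  f <- kfold_partition(23, 10, seed = 2)
  expect_true(all(lengths(f) %in% c(2, 3)))
  expect_identical(sort(unlist(f)), 1:23)

  expect_identical(kfold_partition(57, 7, seed = 9), kfold_partition(57, 7, seed = 9))
  expect_error(kfold_partition(5, 10), ">=")
})

test_that("stratified partition preserves class proportions within one sample", {
  y <- rep(c(1, 2, 3), times = c(70, 20, 10))
  f <- kfold_partition(100, 10, seed = 3, labels = y, stratified = TRUE)
  expect_identical(sort(unlist(f)), 1:100)
  expect_true(all(lengths(f) == 10))
  for (k in seq_along(f)) {
    counts <- table(factor(y[f[[k]]], levels = 1:3))
    expect_true(all(abs(counts - c(7, 2, 1)) <= 1))
  }
})

test_that("bold-driver rule adapts the learning rate with clamping", {
  expect_equal(adapt_learning_rate(0.1, 0.38, 0.40), 0.105)
  expect_equal(adapt_learning_rate(0.105, 0.41, 0.38), 0.0735)
  expect_equal(adapt_learning_rate(1e-6, 0.5, 0.4), 1e-6)    # clamped at floor
  expect_equal(adapt_learning_rate(0.99, 0.3, 0.4), 1)       # clamped at cap
  expect_equal(adapt_learning_rate(0.05, 0.4, NA), 0.05)     # first step
  expect_equal(adapt_learning_rate(0.05, 0.4, 0.4), 0.05)    # unchanged error
})

test_that("a huge error threshold gates off all updates", {
  b <- scaled_blobs(60, seed = 21)
  cfg <- train_config(n_rules = 4, max_epoch = 2, K = 5, delta = 10, seed = 6)
  init <- it2fnn_init(2, 4, 3, seed = 99)
  fit <- it2fnn_train(b$X, b$y, cfg, model = init)
  expect_identical(fit$model$c1, init$c1)
  expect_identical(fit$model$V, init$V)
  expect_identical(fit$model$W, init$W)
})

test_that("training learns separable blobs and keeps coherent history", {
  b <- scaled_blobs(120, seed = 31)
  cfg <- train_config(n_rules = 21, max_epoch = 20, K = 6, seed = 12)
  fit <- it2fnn_train(b$X, b$y, cfg)
  expect_gt(mean(predict(fit$model, b$X) == b$y), 0.9)

  h <- fit$history
  expect_identical(nrow(h), 20L * 6L * 2L)
  expect_setequal(unique(h$split), c("train", "validation"))
  # the checkpointed RMSE is the running minimum of epoch-mean training RMSE
  es <- epoch_summary(fit)
  expect_equal(fit$best_rmse, min(es$train_rmse))
  expect_identical(fit$best_epoch, es$epoch[which.min(es$train_rmse)])
})

test_that("training is bit-reproducible from the configuration seed", {
  b <- scaled_blobs(80, seed = 41)
  cfg <- train_config(n_rules = 5, max_epoch = 3, K = 5, seed = 77)
  f1 <- it2fnn_train(b$X, b$y, cfg)
  f2 <- it2fnn_train(b$X, b$y, cfg)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$history, f2$history)
})

test_that("degenerate training inputs are rejected", {
  expect_error(it2fnn_train(matrix(numeric(0), 0, 2), integer(0),
                            train_config(K = 2)), "empty")
  b <- scaled_blobs(40, seed = 51)
  expect_error(it2fnn_train(b$X, b$y + 3, train_config(K = 2), n_out = 3),
               "labels")
})
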
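# Confusion counts, classification metrics and RMSE reporting.

test_that("one-vs-rest confusion counts are correct and total", {
  counts <- confusion_counts(c(1, 1, 2), c(1, 2, 2), positive_class = 1)
  expect_identical(counts, c(TP = 1L, FP = 0L, TN = 1L, FN = 1L))
  expect_identical(sum(counts), 3L)

  perfect <- confusion_counts(c(1, 2, 1), c(1, 2, 1), 1)
  expect_identical(perfect[["FP"]], 0L)
  expect_identical(perfect[["FN"]], 0L)

  flipped <- confusion_counts(c(1, 2, 1, 2), c(2, 1, 2, 1), 1)
  expect_identical(flipped[["TP"]], 0L)
  expect_identical(flipped[["TN"]], 0L)

  expect_error(confusion_counts(1:3, 1:4, 1), "length")
})

test_that("binary metrics arithmetic matches hand computation", {
  # constructed counts TP=50, FN=5, FP=10, TN=35
  y_true <- rep(c(1, 1, 2, 2), times = c(50, 5, 10, 35))
  y_pred <- rep(c(1, 2, 1, 2), times = c(50, 5, 10, 35))
  m <- classification_metrics(y_true, y_pred, classes = 1)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(m$recall, 50 / 55, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (50 / 60) * (50 / 55) / (50 / 60 + 50 / 55),
               tolerance = 1e-12)
  expect_equal(round(c(m$precision, m$recall, m$f1), 4),
               c(0.8333, 0.9091, 0.8696))
})

test_that("perfect prediction and silent classes behave as defined", {
  y <- rep(1:3, each = 4)
  m <- classification_metrics(y, y)
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1), rep(1, 4))

  # a predictor that never emits class 3: its precision counts as 0
  y_pred <- ifelse(y == 3, 1, y)
  m <- classification_metrics(y, y_pred)
  expect_equal(unname(m$per_class["3", "precision"]), 0)
  expect_equal(m$precision,
               mean(c(m$per_class["1", "precision"],
                      m$per_class["2", "precision"], 0)))
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
})

test_that("macro metrics are invariant under consistent class relabeling", {
  set.seed(10)
  y_true <- sample(1:3, 200, replace = TRUE)
  y_pred <- sample(1:3, 200, replace = TRUE)
  m1 <- classification_metrics(y_true, y_pred)
  relab <- c(3L, 1L, 2L)
  m2 <- classification_metrics(relab[y_true], relab[y_pred])
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$precision, m2$precision, tolerance = 1e-12)
  expect_equal(m1$recall, m2$recall, tolerance = 1e-12)
  expect_equal(m1$f1, m2$f1, tolerance = 1e-12)
})

test_that("metrics agree with an established reference implementation", {
  skip_if_not_installed("caret")
  set.seed(77)
  for (rep in 1:50) {
    y_true <- factor(sample(1:3, 60, replace = TRUE), levels = 1:3)
    y_pred <- factor(sample(1:3, 60, replace = TRUE), levels = 1:3)
    cm <- caret::confusionMatrix(y_pred, y_true)
    ours <- classification_metrics(as.integer(as.character(y_true)),
                                   as.integer(as.character(y_pred)),
                                   classes = 1:3)
    ref_prec <- cm$byClass[, "Pos Pred Value"]
    ref_rec <- cm$byClass[, "Sensitivity"]
    ref_prec[is.na(ref_prec)] <- 0   # zero-division convention
    ref_rec[is.na(ref_rec)] <- 0
    expect_equal(ours$accuracy, unname(cm$overall["Accuracy"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(ours$per_class[, "precision"]), unname(ref_prec),
                 tolerance = 1e-12)
    expect_equal(unname(ours$per_class[, "recall"]), unname(ref_rec),
                 tolerance = 1e-12)
  }
})

test_that("rmse is the root mean squared elementwise deviation", {
  A <- matrix(runif(12), 3, 4)
  expect_identical(rmse(A, A), 0)
  expect_equal(rmse(A + 0.3, A), 0.3, tolerance = 1e-12)
  set.seed(5)
  B <- matrix(rnorm(12), 3, 4)
  expect_equal(rmse(A, B), sqrt(sum((A - B)^2) / 12), tolerance = 1e-12)
  expect_error(rmse(A, matrix(0, 2, 2)), "shape")
})
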
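#' One-vs-rest confusion counts for a class
#'
#' @param y_true,y_pred Equal-length integer label vectors.
#' @param positive_class The class treated as positive.
#' @return Named integer vector with `TP`, `FP`, `TN`, `FN` (summing to the
#'   number of samples).
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  c(TP = sum(pos_t & pos_p), FP = sum(!pos_t & pos_p),
    TN = sum(!pos_t & !pos_p), FN = sum(pos_t & !pos_p))
}

metrics_from_counts <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Accuracy, precision, recall and F1 for multiclass predictions
#'
#' Per-class one-vs-rest precision, recall and F1 are computed from the
#' confusion counts, with the convention that an undefined ratio (zero
#' denominator) counts as 0. Aggregation is macro (unweighted mean over
#' classes) by default; micro pools the counts and weighted averages by class
#' support. Accuracy is always the overall fraction of correct predictions.
#'
#' @param y_true,y_pred Equal-length integer label vectors.
#' @param average `"macro"` (default), `"micro"` or `"weighted"`.
#' @param classes Class codes to evaluate over; defaults to those present in
#'   `y_true`.
#' @return List with `accuracy`, `precision`, `recall`, `f1` and the
#'   `per_class` matrix.
#' @export
classification_metrics <- function(y_true, y_pred,
                                   average = c("macro", "micro", "weighted"),
                                   classes = NULL) {
  average <- match.arg(average)
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  classes <- classes %||% sort(unique(y_true))
  per_class <- t(vapply(classes, function(cl) {
    metrics_from_counts(confusion_counts(y_true, y_pred, cl))
  }, c(precision = 0, recall = 0, f1 = 0)))
  rownames(per_class) <- classes
  accuracy <- mean(y_true == y_pred)
  if (average == "micro") {
    counts <- Reduce(`+`, lapply(classes, function(cl) {
      confusion_counts(y_true, y_pred, cl)
    }))
    agg <- metrics_from_counts(counts)
  } else {
    wts <- if (average == "weighted") {
      as.numeric(vapply(classes, function(cl) sum(y_true == cl), 0))
    } else {
      rep(1, length(classes))
    }
    wts <- wts / sum(wts)
    agg <- colSums(per_class * wts)
  }
  list(accuracy = accuracy, precision = unname(agg[["precision"]]),
       recall = unname(agg[["recall"]]), f1 = unname(agg[["f1"]]),
       per_class = per_class, average = average)
}

#' Root mean square error between output matrices
#'
#' Square root of the mean squared elementwise deviation, the reporting scale
#' used for training, validation and test errors.
#'
#' @param U_pred,U_target Numeric matrices (or vectors) of equal shape.
#' @return Non-negative scalar.
#' @export
rmse <- function(U_pred, U_target) {
  U_pred <- as.matrix(U_pred); U_target <- as.matrix(U_target)
  if (!all(dim(U_pred) == dim(U_target))) {
    stop("matrices differ in shape", call. = FALSE)
  }
  sqrt(mean((U_pred - U_target)^2))
}

#' Assemble a metrics report for a fitted model
#'
#' Mirrors the columns of the usual results table: training, validation and
#' test RMSE plus accuracy, precision, recall and F1 on the evaluation data.
#'
#' @param fit An `it2fnn_fit`.
#' @param X,y Evaluation features (scaled) and labels; the convention of the
#'   design procedure is to re-feed the whole dataset after training.
#' @param average Metric averaging scheme, see [classification_metrics()].
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(fit, X, y, average = "macro") {
  stopifnot(inherits(fit, "it2fnn_fit"))
  X <- as_feature_matrix(X)
  y <- check_labels(y, nrow(X))
  es <- epoch_summary(fit)
  best <- es[es$epoch == fit$best_epoch, ]
  U <- forward_scores(fit$model, X)
  pred <- predict(fit$model, X)
  m <- classification_metrics(y, pred, average = average)
  structure(list(
    n_rules = fit$model$n_rules,
    training_error = best$train_rmse,
    validation_error = best$validation_rmse,
    test_error = rmse(U, one_hot(y, fit$model$n_out)),
    accuracy = m$accuracy, precision = m$precision, recall = m$recall,
    f1 = m$f1, per_class = m$per_class, average = average),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%-8s %-14s %-16s %-10s %-9s %-10s %-7s %-7s\n", "Rules",
              "TrainingError", "ValidationError", "TestError", "Accuracy",
              "Precision", "Recall", "F1"))
  cat(sprintf("%-8d %-14.6f %-16.6f %-10.6f %-9.4f %-10.4f %-7.4f %-7.4f\n",
              x$n_rules, x$training_error, x$validation_error, x$test_error,
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}
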
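#' Full cross-validated pipeline: impute, scale, train, evaluate
#'
#' Convenience front end tying the modules together the way the design
#' procedure runs them: missing cells are filled by the class-conditional
#' imputer, features are min-max scaled (fitted on the full dataset before
#' cross-validation, as the procedure specifies; `scale = "per_fold"` offers
#' the leakage-free alternative where scaler and model are refitted per outer
#' fold), the network is trained by [it2fnn_train()], and the whole dataset
#' is re-fed to the best checkpoint for the final metrics report.
#'
#' @param dataset An `fh_dataset` (see [read_dataset_csv()] or the
#'   generators), or a list with elements `X` and `y`.
#' @param config A [train_config()].
#' @param scale `"global"` (fit the scaler once on all rows, the stated
#'   procedure), `"per_fold"` (outer cross-validation with per-fold scaler
#'   and model fits; reports mean held-out metrics), or `"none"` (data
#'   already scaled).
#' @param impute Fill missing cells with the class-conditional imputer before
#'   scaling.
#' @param average Metric averaging scheme, see [classification_metrics()].
#' @return For `"global"`/`"none"`: a list with `fit`, `report`, `scaler`,
#'   `imputer`. For `"per_fold"`: a list with per-fold reports and their
#'   mean metrics.
#' @export
it2fnn_crossval <- function(dataset, config = train_config(),
                            scale = c("global", "per_fold", "none"),
                            impute = TRUE, average = "macro") {
  scale <- match.arg(scale)
  X <- as_feature_matrix(dataset$X)
  y <- check_labels(dataset$y, nrow(X))

  imputer <- NULL
  if (impute && anyNA(X)) {
    imputer <- fit_imputer(X, y)
    X <- apply_imputer(X, y, imputer)
  }
  if (anyNA(X)) stop("data still contain missing cells; run the imputer",
                     call. = FALSE)

  if (scale == "per_fold") {
    folds <- kfold_partition(nrow(X), config$K, seed = config$seed,
                             labels = y, stratified = config$stratified)
    reports <- lapply(seq_along(folds), function(k) {
      tr <- setdiff(seq_len(nrow(X)), folds[[k]])
      sc <- fit_scaler(X[tr, , drop = FALSE])
      fit <- it2fnn_train(apply_scaler(X[tr, , drop = FALSE], sc), y[tr],
                          config, n_out = max(y))
      metrics_report(fit, apply_scaler(X[folds[[k]], , drop = FALSE], sc),
                     y[folds[[k]]], average = average)
    })
    agg <- sapply(c("test_error", "accuracy", "precision", "recall", "f1"),
                  function(f) mean(vapply(reports, `[[`, 0, f)))
    return(list(fold_reports = reports, mean_metrics = as.list(agg)))
  }

  scaler <- NULL
  if (scale == "global") {
    scaler <- fit_scaler(X)
    X <- apply_scaler(X, scaler)
  }
  fit <- it2fnn_train(X, y, config)
  fit$model$scaler <- scaler
  fit$last_model$scaler <- scaler
  report <- metrics_report(fit, X, y, average = average)
  list(fit = fit, report = report, scaler = scaler, imputer = imputer)
}
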
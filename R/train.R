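#' Training configuration
#'
#' Collects the knobs of the gradient-descent / cross-validation training
#' loop. Defaults follow the design procedure of the network: 10 folds, up to
#' 1000 epochs, type-reduction blend fixed at 0.5/0.5, stochastic per-sample
#' updates gated by the error threshold `delta`.
#'
#' @param n_rules Number of fuzzy rules (model capacity).
#' @param max_epoch Maximum number of training epochs (>= 1).
#' @param K Number of cross-validation folds (>= 2).
#' @param lr Initial learning rate (> 0); adapted per fold by the bold-driver
#'   rule, see [adapt_learning_rate()].
#' @param momentum Momentum rate in `[0, 1)`.
#' @param delta Acceptable per-sample error threshold: a sample whose largest
#'   absolute output residual is at or below `delta` triggers no update.
#' @param seed Integer seed driving initialization, fold assignment and sample
#'   shuffling; the full run is bit-reproducible from it.
#' @param tnorm Rule conjunction, `"prod"` (default) or `"min"`.
#' @param stratified Stratify the fold assignment by class label.
#' @param train_pq Also train the type-reduction blend coefficient `p`
#'   (with `q = 1 - p`); off by default, matching the design procedure whose
#'   update step names only the antecedent centers/widths and the consequent
#'   weights.
#' @param checkpoint Which RMSE drives best-epoch checkpointing: `"train"`
#'   (the procedure as stated) or `"validation"`.
#' @return A `train_config` list.
#' @export
train_config <- function(n_rules = 21L, max_epoch = 1000L, K = 10L, lr = 0.05,
                         momentum = 0.9, delta = 1e-4, seed = 1L,
                         tnorm = c("prod", "min"), stratified = FALSE,
                         train_pq = FALSE,
                         checkpoint = c("train", "validation")) {
  tnorm <- match.arg(tnorm)
  checkpoint <- match.arg(checkpoint)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (max_epoch < 1) stop("max_epoch must be >= 1", call. = FALSE)
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (n_rules < 1) stop("n_rules must be >= 1", call. = FALSE)
  structure(list(n_rules = as.integer(n_rules), max_epoch = as.integer(max_epoch),
                 K = as.integer(K), lr = lr, momentum = momentum, delta = delta,
                 seed = as.integer(seed), tnorm = tnorm,
                 stratified = isTRUE(stratified), train_pq = isTRUE(train_pq),
                 checkpoint = checkpoint),
            class = "train_config")
}

#' Squared-error loss for one sample
#'
#' The per-sample training error is the sum of squared deviations between the
#' desired and current output vectors, \eqn{E = \sum_k (u^d_k - u_k)^2}; the
#' gradient-descent updates differentiate exactly this quantity.
#'
#' @param u Current output vector.
#' @param u_d Desired (target) output vector of the same length.
#' @return Non-negative scalar.
#' @export
sample_error <- function(u, u_d) {
  if (length(u) != length(u_d)) {
    stop("output and target vectors differ in length", call. = FALSE)
  }
  sum((u_d - u)^2)
}

#' Analytic gradients of the per-sample loss
#'
#' Differentiates [sample_error()] through the full forward pass:
#' type reduction, local linear consequents, rule firing and the piecewise
#' membership envelopes. On the piecewise upper membership the active branch's
#' derivative is used; at branch boundaries the interior (value-1) branch
#' applies, whose derivative is zero.
#'
#' @param model An `it2fnn` model.
#' @param x Input vector of length `model$m`.
#' @param u_d Target vector of length `model$n_out`.
#' @return List with gradient arrays `c1`, `c2`, `sigma` (`n_rules x m`),
#'   `V` (`m x n_rules`), `W` (`n_rules x p`), scalar `p_coef` (under the
#'   constraint `q = 1 - p`), plus the forward output `u` and loss `E`.
#' @export
it2fnn_gradients <- function(model, x, u_d) {
  stopifnot(inherits(model, "it2fnn"))
  cpp_backward(model$c1, model$c2, model$sigma, model$V, model$W,
               model$p_coef, model$q_coef, as.numeric(x), as.numeric(u_d),
               identical(model$tnorm, "min"))
}

# Zero-filled velocity state matching a model's trainable parameters.
zero_velocity <- function(model) {
  z <- function(a) array(0, dim(a))
  list(c1 = z(model$c1), c2 = z(model$c2), sigma = z(model$sigma),
       V = z(model$V), W = z(model$W), p_coef = 0)
}

#' Momentum update with invariant repair
#'
#' Applies one momentum step, `velocity <- momentum * velocity - lr * grad`
#' then `parameter <- parameter + velocity`, followed by invariant repair:
#' widths are floored at 1e-4 and any center pair left with `c1 > c2` is
#' swapped.
#'
#' @param model An `it2fnn` model.
#' @param grads Gradient list as returned by [it2fnn_gradients()].
#' @param lr Learning rate.
#' @param momentum Momentum rate.
#' @param velocity Velocity state (same shapes as the parameters); defaults to
#'   all zeros.
#' @return List with the updated `model` and `velocity`.
#' @export
update_parameters <- function(model, grads, lr, momentum = 0,
                              velocity = zero_velocity(model)) {
  stopifnot(inherits(model, "it2fnn"))
  for (nm in c("c1", "c2", "sigma", "V", "W")) {
    velocity[[nm]] <- momentum * velocity[[nm]] - lr * grads[[nm]]
    model[[nm]] <- model[[nm]] + velocity[[nm]]
  }
  model$sigma[model$sigma < 1e-4] <- 1e-4
  flip <- model$c1 > model$c2
  if (any(flip)) {
    tmp <- model$c1[flip]
    model$c1[flip] <- model$c2[flip]
    model$c2[flip] <- tmp
  }
  list(model = model, velocity = velocity)
}

#' Disjoint K-fold partition of sample indices
#'
#' Splits `1..n_samples` into `K` disjoint index sets whose sizes differ by at
#' most one, reproducibly from `seed`. With `stratified = TRUE` and labels
#' supplied, class members are dealt round-robin so per-class proportions are
#' preserved within one sample per fold.
#'
#' @param n_samples Number of samples (>= K).
#' @param K Number of folds.
#' @param seed Integer seed.
#' @param labels Optional class labels (required when `stratified`).
#' @param stratified Preserve per-class proportions across folds.
#' @return List of `K` sorted integer index vectors.
#' @export
kfold_partition <- function(n_samples, K, seed = 1L, labels = NULL,
                            stratified = FALSE) {
  if (n_samples < K) stop("n_samples must be >= K", call. = FALSE)
  if (stratified && is.null(labels)) {
    stop("stratified partition requires labels", call. = FALSE)
  }
  with_seed(seed, {
    fold_of <- integer(n_samples)
    if (stratified) {
      pos <- 0L  # dealing position continues across classes to balance sizes
      for (cl in sort(unique(labels))) {
        members <- sample(which(labels == cl))
        fold_of[members] <- (seq_along(members) + pos - 1L) %% K + 1L
        pos <- (pos + length(members)) %% K
      }
    } else {
      shuffled <- sample.int(n_samples)
      sizes <- rep(n_samples %/% K, K)
      extra <- n_samples %% K
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      fold_of[shuffled] <- rep.int(seq_len(K), sizes)
    }
    lapply(seq_len(K), function(k) which(fold_of == k))
  })
}

#' Bold-driver learning-rate adaptation
#'
#' Grows the learning rate by 5% after the training error decreased and cuts
#' it to 70% after it increased, clamped to `[1e-6, 1]`. An unchanged error
#' (or no previous error) leaves the rate untouched.
#'
#' @param lr Current learning rate (> 0).
#' @param train_error_now Training error of the step just completed.
#' @param train_error_prev Training error of the previous step; `NA` on the
#'   first step.
#' @return Adapted learning rate.
#' @export
adapt_learning_rate <- function(lr, train_error_now, train_error_prev) {
  stopifnot(lr > 0)
  if (is.na(train_error_prev)) return(lr)
  if (train_error_now < train_error_prev) {
    lr <- lr * 1.05
  } else if (train_error_now > train_error_prev) {
    lr <- lr * 0.7
  }
  min(max(lr, 1e-6), 1)
}

model_params_from <- function(model, res) {
  model$c1 <- res$c1; model$c2 <- res$c2; model$sigma <- res$sigma
  model$V <- res$V; model$W <- res$W
  model$p_coef <- res$p_coef; model$q_coef <- res$q_coef
  model
}

#' Train a T2-FNN by stochastic gradient descent under K-fold cross-validation
#'
#' Implements the full design loop. Per epoch, each of the `K` folds in turn
#' is held out: the model is updated sample-by-sample (in a per-epoch shuffled
#' order) on the remaining `K - 1` folds, skipping samples whose error is
#' within `delta`; RMSE on the held-out fold is recorded as validation, and
#' the epoch-mean training RMSE drives the bold-driver learning rate.
#' After each epoch the parameters are checkpointed whenever the epoch's
#' training RMSE improves on the best seen so far; the checkpointed model is
#' returned.
#'
#' @param X Feature matrix (`N x m`), scaled to `[0, 1]`.
#' @param y Integer class labels in `1..p` (targets are one-hot encoded).
#' @param config A [train_config()].
#' @param model Optional starting model; by default a fresh [it2fnn_init()]
#'   drawn from the configuration seed.
#' @param n_out Number of classes; defaults to `max(y)`.
#' @return An `it2fnn_fit` list: `model` (best checkpoint), `last_model`,
#'   `history` (data frame with columns epoch, fold, split, rmse),
#'   `best_epoch`, `best_rmse`, `folds`, `config`, `final_lr`.
#' @examples
#' d <- generate_blobs(60, n_classes = 3, separation = 6, seed = 1)
#' X <- apply_scaler(d$X, fit_scaler(d$X))
#' fit <- it2fnn_train(X, d$y, train_config(n_rules = 5, max_epoch = 3, K = 5))
#' fit$best_rmse
#' @export
it2fnn_train <- function(X, y, config = train_config(), model = NULL,
                         n_out = NULL) {
  stopifnot(inherits(config, "train_config"))
  X <- as_feature_matrix(X)
  N <- nrow(X)
  if (N == 0L) stop("empty dataset", call. = FALSE)
  y <- check_labels(y, N)
  p <- as.integer(n_out %||% max(y))
  if (p < 2) stop("need at least two classes", call. = FALSE)
  if (any(y < 1L | y > p)) stop("labels must lie in 1..", p, call. = FALSE)
  Ud <- one_hot(y, p)
  tnorm_min <- identical(config$tnorm, "min")

  with_seed(config$seed, {
    if (is.null(model)) {
      # draw the init from a seed taken off this run's RNG stream
      model <- it2fnn_init(ncol(X), config$n_rules, p,
                           seed = sample.int(.Machine$integer.max, 1L),
                           tnorm = config$tnorm)
    } else {
      stopifnot(inherits(model, "it2fnn"))
      if (model$m != ncol(X) || model$n_out != p) {
        stop("supplied model does not match the data dimensions", call. = FALSE)
      }
    }
    folds <- kfold_partition(N, config$K,
                             seed = sample.int(.Machine$integer.max, 1L),
                             labels = y, stratified = config$stratified)
    vel <- zero_velocity(model)
    lr <- config$lr
    prev_rmse <- NA_real_
    best_rmse <- Inf
    best_model <- model
    best_epoch <- NA_integer_
    hist_epoch <- integer(0); hist_fold <- integer(0)
    hist_split <- character(0); hist_rmse <- numeric(0)

    for (epoch in seq_len(config$max_epoch)) {
      fold_train_rmse <- numeric(config$K)
      fold_val_rmse <- numeric(config$K)
      for (k in seq_len(config$K)) {
        val_idx <- folds[[k]]
        train_idx <- setdiff(seq_len(N), val_idx)
        order <- train_idx[sample.int(length(train_idx))]
        res <- cpp_sgd_pass(model$c1, model$c2, model$sigma, model$V, model$W,
                            model$p_coef, model$q_coef, X, Ud, order,
                            lr, config$momentum, config$delta, tnorm_min,
                            config$train_pq, vel$c1, vel$c2, vel$sigma,
                            vel$V, vel$W, vel$p_coef)
        model <- model_params_from(model, res)
        vel <- list(c1 = res$vc1, c2 = res$vc2, sigma = res$vsigma,
                    V = res$vV, W = res$vW, p_coef = res$vp)
        fold_train_rmse[k] <- rmse(forward_scores(model, X[train_idx, , drop = FALSE]),
                                   Ud[train_idx, , drop = FALSE])
        fold_val_rmse[k] <- rmse(forward_scores(model, X[val_idx, , drop = FALSE]),
                                 Ud[val_idx, , drop = FALSE])
      }
      # bold-driver adaptation on like-for-like quantities: the epoch-mean
      # training RMSE (per-fold comparisons would mix subset noise into the
      # rate and shrink it towards the floor)
      lr <- adapt_learning_rate(lr, mean(fold_train_rmse), prev_rmse)
      prev_rmse <- mean(fold_train_rmse)
      hist_epoch <- c(hist_epoch, rep(epoch, 2L * config$K))
      hist_fold <- c(hist_fold, rep(seq_len(config$K), each = 2L))
      hist_split <- c(hist_split, rep(c("train", "validation"), config$K))
      hist_rmse <- c(hist_rmse, as.numeric(rbind(fold_train_rmse, fold_val_rmse)))
      epoch_rmse <- if (config$checkpoint == "validation") {
        mean(fold_val_rmse)
      } else {
        mean(fold_train_rmse)
      }
      if (epoch_rmse < best_rmse) {
        best_rmse <- epoch_rmse
        best_model <- model
        best_epoch <- epoch
      }
    }

    history <- data.frame(epoch = hist_epoch, fold = hist_fold,
                          split = hist_split, rmse = hist_rmse,
                          stringsAsFactors = FALSE)
    structure(list(model = best_model, last_model = model, history = history,
                   best_epoch = best_epoch, best_rmse = best_rmse,
                   folds = folds, config = config, final_lr = lr),
              class = "it2fnn_fit")
  })
}

#' @export
print.it2fnn_fit <- function(x, ...) {
  cat("T2-FNN cross-validated fit\n")
  cat(sprintf("  rules: %d   folds: %d   epochs run: %d\n",
              x$model$n_rules, x$config$K, max(x$history$epoch)))
  cat(sprintf("  best epoch: %d   best %s RMSE: %.6f\n",
              x$best_epoch, x$config$checkpoint, x$best_rmse))
  invisible(x)
}

#' Epoch-level RMSE summary of a training history
#'
#' @param fit An `it2fnn_fit`.
#' @return Data frame with one row per epoch and mean train/validation RMSE.
#' @export
epoch_summary <- function(fit) {
  h <- fit$history
  tr <- tapply(h$rmse[h$split == "train"], h$epoch[h$split == "train"], mean)
  va <- tapply(h$rmse[h$split == "validation"], h$epoch[h$split == "validation"], mean)
  data.frame(epoch = as.integer(names(tr)), train_rmse = as.numeric(tr),
             validation_rmse = as.numeric(va))
}
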
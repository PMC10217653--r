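#' Fit a per-feature min-max scaler
#'
#' Records per-feature minima and maxima, ignoring missing cells, for scaling
#' to \eqn{[0, 1]}.
#'
#' @param X Feature matrix or data frame.
#' @return A `minmax_scaler` with fields `min`, `max` and `feature_names`.
#' @export
fit_scaler <- function(X) {
  X <- as_feature_matrix(X)
  mins <- apply(X, 2L, min, na.rm = TRUE)
  maxs <- apply(X, 2L, max, na.rm = TRUE)
  structure(list(min = mins, max = maxs, feature_names = colnames(X)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature through `(x - min) / (max - min)`; values outside the
#' fitted range clip to \eqn{[0, 1]}. A constant feature scales to 0 with a
#' warning. Missing cells stay missing.
#'
#' @param X Feature matrix or data frame.
#' @param state A fitted [fit_scaler()] object.
#' @return Scaled matrix of the same shape.
#' @export
apply_scaler <- function(X, state) {
  stopifnot(inherits(state, "minmax_scaler"))
  X <- as_feature_matrix(X)
  if (ncol(X) != length(state$min)) {
    stop("scaler was fitted on ", length(state$min), " features", call. = FALSE)
  }
  rng <- state$max - state$min
  const <- rng <= 0
  if (any(const)) {
    warning("constant feature(s) scaled to 0: ",
            paste(which(const), collapse = ", "), call. = FALSE)
  }
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- if (const[j]) 0 else (X[, j] - state$min[j]) / rng[j]
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Invert a min-max scaling
#'
#' @param X Scaled matrix in `[0, 1]`.
#' @param state A fitted [fit_scaler()] object.
#' @return Matrix on the original feature scale (constant features recover
#'   their fitted minimum).
#' @export
inverse_scaler <- function(X, state) {
  stopifnot(inherits(state, "minmax_scaler"))
  X <- as_feature_matrix(X)
  rng <- state$max - state$min
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- X[, j] * rng[j] + state$min[j]
  }
  out
}

#' Fit the class-conditional linear-interpolation imputer
#'
#' For every feature with missing cells, the observed value range
#' \eqn{[x_{min}, x_{max}]} and the range of co-occurring class codes
#' \eqn{[y_1, y_2]} are each divided into `nc - 1` equal steps
#' (\eqn{\Delta x = (x_{max}-x_{min})/(nc-1)},
#' \eqn{\Delta y = (y_2-y_1)/(nc-1)}), giving paired cluster centers
#' \eqn{x_{ck} = x_{min} + (k-1)\Delta x} and
#' \eqn{y_{ck} = y_1 + (k-1)\Delta y} that encode an assumed linear
#' input-output relationship. The relationship's direction is estimated from
#' the sign of the correlation between observed values and class codes; a
#' negative sign reverses the class-to-center mapping so a linearly
#' *decreasing* feature maps class 1 to \eqn{x_{max}}.
#'
#' @param X Feature matrix or data frame (original or scaled units).
#' @param y_labels Class codes in `1..nc`.
#' @param missing_mask Logical matrix marking missing cells; defaults to
#'   `is.na(X)`.
#' @return A `class_imputer` with one centers entry per affected feature.
#' @export
fit_imputer <- function(X, y_labels, missing_mask = NULL) {
  X <- as_feature_matrix(X)
  y <- check_labels(y_labels, nrow(X))
  mask <- missing_mask %||% is.na(X)
  if (!all(dim(mask) == dim(X))) stop("mask shape mismatch", call. = FALSE)
  nc <- length(unique(y))
  if (nc < 2) stop("need at least two output classes", call. = FALSE)
  affected <- which(colSums(mask) > 0)
  feats <- list()
  for (f in affected) {
    obs <- !mask[, f] & !is.na(X[, f])
    if (!any(obs)) {
      stop("feature ", f, " is entirely missing; cannot fit centers",
           call. = FALSE)
    }
    if (sum(obs) < 2) {
      stop("feature ", f, " needs at least 2 observed values", call. = FALSE)
    }
    xv <- X[obs, f]
    yv <- y[obs]
    x_min <- min(xv); x_max <- max(xv)
    y1 <- min(yv); y2 <- max(yv)
    dx <- (x_max - x_min) / (nc - 1)
    dy <- (y2 - y1) / (nc - 1)
    direction <- 1
    if (sd(xv) > 0 && sd(yv) > 0) {
      rho <- cor(xv, as.numeric(yv))
      if (is.finite(rho) && rho < 0) direction <- -1
    }
    feats[[as.character(f)]] <- list(
      feature = f,
      x_centers = x_min + (seq_len(nc) - 1) * dx,
      y_centers = y1 + (seq_len(nc) - 1) * dy,
      delta_x = dx, delta_y = dy, direction = direction)
  }
  structure(list(nc = nc, n_features = ncol(X), features = feats),
            class = "class_imputer")
}

#' Impute missing cells from class-conditional centers
#'
#' Each missing cell is replaced by the input cluster center paired with the
#' row's output class (nearest output center when class codes and centers do
#' not coincide exactly); observed cells are never altered, so the operation
#' is idempotent.
#'
#' @param X Feature matrix with missing cells as `NA`.
#' @param y_labels Class codes; a row holding a missing cell must have a valid
#'   label, since the mapping is driven by the output class.
#' @param model A fitted [fit_imputer()] object.
#' @return `X` with all missing cells filled.
#' @export
apply_imputer <- function(X, y_labels, model) {
  stopifnot(inherits(model, "class_imputer"))
  X <- as_feature_matrix(X)
  if (ncol(X) != model$n_features) {
    stop("imputer was fitted on ", model$n_features, " features", call. = FALSE)
  }
  if (!is.numeric(y_labels) || length(y_labels) != nrow(X)) {
    stop("labels must be numeric and match the number of rows", call. = FALSE)
  }
  missing_cols <- which(colSums(is.na(X)) > 0)
  for (f in missing_cols) {
    entry <- model$features[[as.character(f)]]
    if (is.null(entry)) {
      stop("no imputation centers fitted for feature ", f, call. = FALSE)
    }
    rows <- which(is.na(X[, f]))
    cls <- y_labels[rows]
    if (anyNA(cls) || any(cls != round(cls))) {
      stop("rows with missing cells require valid class labels", call. = FALSE)
    }
    k <- vapply(cls, function(cc) which.min(abs(entry$y_centers - cc)), 1L)
    pos <- if (entry$direction >= 0) k else model$nc + 1L - k
    X[rows, f] <- entry$x_centers[pos]
  }
  X
}

#' Erase random cells to create a missing-data mask
#'
#' Sets exactly `count` distinct feature cells to `NA`, uniformly at random
#' and reproducibly from `seed`.
#'
#' @param X Feature matrix or data frame.
#' @param count Number of cells to erase (at most `nrow(X) * ncol(X)`).
#' @param seed Integer seed.
#' @return List with the masked matrix `X` and the logical `mask` of erased
#'   positions.
#' @export
inject_missing <- function(X, count, seed = 1L) {
  X <- as_feature_matrix(X)
  total <- length(X)
  if (count > total) stop("count exceeds the number of cells", call. = FALSE)
  if (count < 0) stop("count must be non-negative", call. = FALSE)
  mask <- matrix(FALSE, nrow(X), ncol(X))
  if (count > 0) {
    cells <- with_seed(seed, sample.int(total, count))
    mask[cells] <- TRUE
    X[cells] <- NA_real_
  }
  list(X = X, mask = mask)
}
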
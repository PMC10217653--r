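# Synthetic data generators: a CTG-like table matched to the per-feature
# moments of the public 2126-record fetal-health cardiotocography dataset,
# separable Gaussian blobs as a training testbed, and an exactly-linear
# single-feature toy for the imputer.

new_dataset <- function(X, y, feature_names = colnames(X), missing_mask = NULL) {
  X <- as_feature_matrix(X)
  colnames(X) <- feature_names
  structure(list(X = X, y = as.integer(y), feature_names = feature_names,
                 missing_mask = missing_mask),
            class = "fh_dataset")
}

#' @export
print.fh_dataset <- function(x, ...) {
  cat(sprintf("Tabular classification dataset: %d rows, %d features, %d classes\n",
              nrow(x$X), ncol(x$X), length(unique(x$y))))
  cat("  class counts:", paste(sprintf("%d=%d", sort(unique(x$y)),
                                       table(x$y)), collapse = ", "), "\n")
  if (!is.null(x$missing_mask)) {
    cat("  missing cells:", sum(x$missing_mask), "\n")
  }
  invisible(x)
}

#' Per-feature moment specifications of the cardiotocography table
#'
#' The packaged table of per-feature mean, standard deviation, minimum and
#' maximum for the 21 CTG-derived features (FHR baseline, acceleration and
#' deceleration rates, variability summaries and FHR-histogram statistics) of
#' the public 2126-record fetal-health cardiotocography dataset, together
#' with the flag marking the features given class-dependent mean shifts by
#' [generate_ctg_like()].
#'
#' @return Data frame with columns `name`, `mean`, `std`, `min`, `max`,
#'   `class_shifted`.
#' @export
ctg_feature_specs <- function() {
  path <- system.file("extdata", "ctg_feature_moments.csv", package = "it2fnn")
  specs <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  specs$class_shifted <- specs$class_shifted == 1
  specs
}

# Rejection sampling from N(mean, sd) restricted to [lo, hi] (all arguments
# recycled to length n); clipping fallback after `tries` rounds keeps the
# generator total.
rtrunc_norm <- function(n, mean, sd, lo, hi, tries = 50L) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  if (all(sd <= 0)) return(pmin(pmax(mean, lo), hi))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  t <- 0L
  while (length(bad) && t < tries) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lo[bad] | x[bad] > hi[bad]]
    t <- t + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lo[bad]), hi[bad])
  x
}

# Per-class mean-shift multipliers (units of one feature std). The weights
# solve sum(proportions * shift) = 0 so the marginal mean stays on target
# while Suspect and Pathological rows drift upward relative to Normal.
class_shift_weights <- function(proportions, magnitude = 0.5) {
  d <- c(0, 0.5, 1)[seq_along(proportions)]
  if (proportions[1] > 0) {
    d[1] <- -sum(proportions[-1] * d[-1]) / proportions[1]
  }
  magnitude * d
}

#' Generate a CTG-like synthetic dataset
#'
#' Draws 21 feature columns from truncated normals with the packaged
#' per-feature (mean, std), clipped to the recorded `[min, max]` after a
#' rejection-sampling budget. Rows are assigned to the three fetal-health
#' classes (1 = Normal, 2 = Suspect, 3 = Pathological) with the given
#' proportions; a designated subset of clinically salient features receives
#' class-dependent mean shifts of at most `shift` standard deviations,
#' balanced across classes so the marginal moments stay on the packaged
#' targets, which makes the classes learnable without distorting the table's
#' statistics.
#'
#' @param n Number of rows (>= 10).
#' @param class_proportions Length-3 proportions summing to 1; the default
#'   (0.78, 0.14, 0.08) reflects the imbalance implied by a label mean near
#'   1.30.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param shift Maximum class shift in feature standard deviations.
#' @return An `fh_dataset` with fields `X` (`n x 21`), `y`, `feature_names`.
#' @examples
#' d <- generate_ctg_like(200, seed = 42)
#' colMeans(d$X)[1]
#' @export
generate_ctg_like <- function(n, class_proportions = c(0.78, 0.14, 0.08),
                              seed = 1L, shift = 0.5) {
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (length(class_proportions) != 3 || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  specs <- ctg_feature_specs()
  dshift <- class_shift_weights(class_proportions, shift)
  with_seed(seed, {
    y <- sample.int(3L, n, replace = TRUE, prob = class_proportions)
    X <- matrix(0, n, nrow(specs))
    for (f in seq_len(nrow(specs))) {
      s <- specs[f, ]
      mu <- if (s$class_shifted) s$mean + dshift[y] * s$std else s$mean
      X[, f] <- rtrunc_norm(n, mu, s$std, s$min, s$max)
    }
    new_dataset(X, y, specs$name)
  })
}

#' Generate well-separated Gaussian blobs
#'
#' Isotropic Gaussian clusters with unit within-class standard deviation and
#' centers a fixed distance apart (regular-simplex placement when the number
#' of classes allows, a circle otherwise). Labels are balanced up to
#' remainder. Serves as a learnability testbed for the trainer.
#'
#' @param n Number of samples.
#' @param n_classes Number of clusters/classes (>= 2).
#' @param separation Pairwise distance between cluster centers.
#' @param m Dimensionality (default 2).
#' @param sd Within-cluster standard deviation.
#' @param seed Integer seed.
#' @return An `fh_dataset`.
#' @export
generate_blobs <- function(n, n_classes = 3L, separation = 4, m = 2L, sd = 1,
                           seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  centers <- blob_centers(n_classes, m, separation)
  with_seed(seed, {
    y <- rep_len(seq_len(n_classes), n)
    X <- centers[y, , drop = FALSE] + matrix(rnorm(n * m, sd = sd), n, m)
    colnames(X) <- paste0("x", seq_len(m))
    d <- new_dataset(X, y)
    d$centers <- centers
    d
  })
}

# Cluster centers with pairwise distance `separation`: regular simplex when
# n_classes <= m + 1, otherwise equally spaced on a circle in the first two
# dimensions.
blob_centers <- function(n_classes, m, separation) {
  if (n_classes <= m + 1) {
    # vertices of a regular simplex, edge length sqrt(2), then rescaled
    E <- diag(n_classes)
    E <- E - matrix(colMeans(E), n_classes, n_classes, byrow = TRUE)
    Q <- qr.Q(qr(t(E)))[, seq_len(n_classes - 1L), drop = FALSE]
    V <- E %*% Q
    V <- V * separation / sqrt(sum((V[1, ] - V[2, ])^2))
    centers <- matrix(0, n_classes, m)
    centers[, seq_len(ncol(V))] <- V
  } else {
    if (m < 2) stop("need m >= 2 for more than m + 1 classes", call. = FALSE)
    radius <- separation / (2 * sin(pi / n_classes))
    theta <- 2 * pi * (seq_len(n_classes) - 1) / n_classes
    centers <- matrix(0, n_classes, m)
    centers[, 1] <- radius * cos(theta)
    centers[, 2] <- radius * sin(theta)
  }
  centers
}

#' Generate an exactly linear class-to-feature toy dataset
#'
#' One feature whose class-conditional values sit exactly on the imputer's
#' cluster centers for a linear class-to-value map over `x_range`:
#' increasing (`direction = +1`) maps class 1 to `x_range[1]` and class `nc`
#' to `x_range[2]`; decreasing (`direction = -1`) reverses the mapping. Used
#' for exact-recovery checks of the imputer.
#'
#' @param n Number of rows.
#' @param nc Number of classes (>= 2).
#' @param direction `+1` (increasing) or `-1` (decreasing).
#' @param x_range Feature range covered by the class centers.
#' @param seed Integer seed (shuffles the row order only).
#' @return An `fh_dataset` with a single feature column.
#' @export
generate_linear_response <- function(n, nc = 3L, direction = 1, x_range = c(0, 1),
                                     seed = 1L) {
  if (nc < 2) stop("nc must be >= 2", call. = FALSE)
  centers <- seq(x_range[1], x_range[2], length.out = nc)
  if (direction < 0) centers <- rev(centers)
  with_seed(seed, {
    y <- sample(rep_len(seq_len(nc), n))
    X <- matrix(centers[y], ncol = 1L)
    colnames(X) <- "x1"
    new_dataset(X, y)
  })
}
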
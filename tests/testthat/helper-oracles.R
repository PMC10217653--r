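# Independent oracles used by the tests. These deliberately re-derive results
# through different code paths (explicit loops, finite differences, analytic
# truncated-normal moments) so they never share code with the implementation
# they check.

# Type-1 TSK fuzzy system, loop-based: Gaussian memberships
# exp(-(x - c)^2 / sigma^2), product conjunction, weighted-mean defuzzification.
tsk_type1_forward <- function(centers, sigma, V, W, x) {
  n <- nrow(centers); m <- ncol(centers); p <- ncol(W)
  f <- numeric(n)
  y <- numeric(n)
  for (j in seq_len(n)) {
    fj <- 1
    for (i in seq_len(m)) {
      fj <- fj * exp(-(x[i] - centers[j, i])^2 / sigma[j, i]^2)
    }
    f[j] <- fj
    y[j] <- sum(x * V[, j])
  }
  u <- numeric(p)
  for (k in seq_len(p)) {
    u[k] <- sum(f * y * W[, k]) / sum(f)
  }
  u
}

# Central finite differences of the per-sample squared-error loss with respect
# to every model parameter, evaluated through the R-level forward pass.
fd_gradients <- function(model, x, u_d, h = 1e-6) {
  loss <- function(mod) sample_error(it2fnn_forward(mod, x), u_d)
  fd_mat <- function(name) {
    g <- model[[name]]
    for (idx in seq_along(g)) {
      up <- model; up[[name]][idx] <- up[[name]][idx] + h
      dn <- model; dn[[name]][idx] <- dn[[name]][idx] - h
      g[idx] <- (loss(up) - loss(dn)) / (2 * h)
    }
    g
  }
  list(c1 = fd_mat("c1"), c2 = fd_mat("c2"), sigma = fd_mat("sigma"),
       V = fd_mat("V"), W = fd_mat("W"))
}

expect_grad_close <- function(analytic, fd, tol = 1e-5) {
  for (nm in c("c1", "c2", "sigma", "V", "W")) {
    err <- abs(analytic[[nm]] - fd[[nm]]) / pmax(1, abs(fd[[nm]]))
    expect_lt(max(err), tol)
  }
}

# Mean and standard deviation of a normal truncated to [lo, hi], from the
# standard closed forms.
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  mu <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = mu, sd = sqrt(v))
}

# A small random model without going through it2fnn_init (keeps the path to
# the constructor exercised independently in some tests).
random_small_model <- function(m, n, p, seed) {
  it2fnn_init(m = m, n_rules = n, n_out = p, seed = seed)
}

# fresh path in the session temp directory
withr_local_file <- function(name) {
  path <- file.path(tempdir(), name)
  if (file.exists(path)) unlink(path)
  path
}

# seeded draw for test fixtures
with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}

scaled_blobs <- function(n = 300, seed = 11, separation = 8) {
  d <- generate_blobs(n, n_classes = 3, separation = separation, seed = seed)
  sc <- fit_scaler(d$X)
  list(X = apply_scaler(d$X, sc), y = d$y, raw = d, scaler = sc)
}
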
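# Independent oracles used to cross-check the implementation. Each is coded
# directly from the defining equations, sharing no code with the package.

# Ordinary least squares predictions via the normal equations.
ols_predict <- function(X, y, Xnew = X) {
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  drop(cbind(1, Xnew) %*% beta)
}

# PLS1 built on svd(): at each step the weight vector is the leading left
# singular vector of the residual cross-covariance X'y, followed by explicit
# score/loading deflation. Returns the coefficient vector for A components.
svd_pls_coef <- function(X, y, A) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  for (a in seq_len(A)) {
    s <- svd(crossprod(Xc, matrix(yc)))
    w <- s$u[, 1]
    t <- Xc %*% w
    tt <- sum(t^2)
    P[, a] <- crossprod(Xc, t) / tt
    q[a] <- sum(yc * t) / tt
    W[, a] <- w
    Xc <- Xc - t %*% t(P[, a])
    yc <- yc - q[a] * t
  }
  drop(W %*% solve(t(P) %*% W, q))
}

# SPXY greedy trace re-implemented literally from its definition.
spxy_oracle <- function(X, y, n_cal) {
  n <- nrow(X)
  dx <- as.matrix(dist(X))
  dy <- abs(outer(y, y, `-`))
  d <- dx / max(dx) + (if (max(dy) > 0) dy / max(dy) else 0)
  best <- -Inf; pair <- c(1L, 2L)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (d[i, j] > best) { best <- d[i, j]; pair <- c(i, j) }
  sel <- pair
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    score <- vapply(rest, function(r) min(d[r, sel]), numeric(1))
    sel <- c(sel, rest[which.max(score)])
  }
  sort(sel)
}

# Backward interval elimination re-implemented from the greedy rule, using a
# caller-supplied RMSECV function so the oracle tests the elimination logic
# against any fitness.
bipls_oracle <- function(intervals, fitness) {
  alive <- seq_along(intervals)
  states <- list(list(alive = alive, rmsecv = fitness(unlist(intervals[alive]))))
  while (length(alive) > 1) {
    cand <- vapply(seq_along(alive), function(j)
      fitness(unlist(intervals[alive[-j]])), numeric(1))
    alive <- alive[-which.min(cand)]
    states[[length(states) + 1]] <-
      list(alive = alive, rmsecv = fitness(unlist(intervals[alive])))
  }
  states[[which.min(vapply(states, `[[`, numeric(1), "rmsecv"))]]
}

# Small low-rank regression problem: y depends on `n_factors` latent
# directions of X plus noise.
make_factor_data <- function(n, p, n_factors, noise_sd, seed) {
  set.seed(seed)
  T <- matrix(rnorm(n * n_factors), n)
  L <- matrix(rnorm(n_factors * p), n_factors)
  X <- T %*% L + matrix(rnorm(n * p, 0, 1e-3), n)
  y <- drop(T %*% rnorm(n_factors)) + rnorm(n, 0, noise_sd)
  list(X = X, y = y)
}

# Tiny stover-like dataset for selector tests.
make_small_sim <- function(n = 50, p = 120, seed = 1, ...) {
  generate_spectra(default_stover_spec(n_samples = n, n_points = p, ...),
                   seed = seed)
}
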
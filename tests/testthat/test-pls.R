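test_that("one-factor data is fit exactly with a single component", {
  set.seed(31)
  w <- c(2, -1, rep(0, 8))
  X1 <- outer(rnorm(20), rnorm(10))  # rank-1 X, y along its single factor
  y1 <- drop(X1 %*% w)
  m <- fit_pls(X1, y1, 1)
  expect_lt(sqrt(sum((predict(m, X1) - y1)^2)), 1e-8 * sqrt(sum(y1^2)))
})

test_that("full-rank NIPALS predictions equal OLS", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(50), 10, 5)
    y <- rnorm(10)
    m <- fit_pls(X, y, 5)
    expect_equal(predict(m, X), ols_predict(X, y), tolerance = 1e-8)
  }
})

test_that("coefficients agree with the SVD-deflation oracle at small A", {
  for (s in 1:5) for (A in 1:3) {
    set.seed(100 + s)
    X <- matrix(rnorm(80), 16, 5)
    y <- rnorm(16)
    m <- fit_pls(X, y, A)
    b_oracle <- svd_pls_coef(X, y, A)
    expect_lt(max(abs(m$b - b_oracle)) / max(abs(b_oracle)), 1e-6)
  }
})

test_that("degenerate fits behave: constant y, rank truncation, input checks", {
  X <- matrix(rnorm(30), 10, 3)
  m <- fit_pls(X, rep(5, 10), 2)
  expect_equal(m$b, rep(0, 3))
  expect_equal(predict(m, X), rep(5, 10))
  expect_true(m$truncated)
  # rank-1 X cannot support 3 components
  X1 <- outer(1:10, c(1, 2, 3)) + 0
  m1 <- fit_pls(X1, rnorm(10), 3)
  expect_lt(m1$A, 3)
  expect_error(fit_pls(X[1:2, ], 1:2, 1), "at least 3")
  expect_error(fit_pls(X, rnorm(10), 4), "A must be")
  expect_error(predict(m, X[, 1:2]), "columns")
})

test_that("predict is consistent with centering and refit invariance", {
  set.seed(33)
  X <- matrix(rnorm(120), 20, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(20, 0, 0.1)
  m <- fit_pls(X, y, 3)
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean)
  # affine shift of X with a refit leaves predictions unchanged
  shift <- rnorm(6)
  m2 <- fit_pls(sweep(X, 2, shift, "+"), y, 3)
  expect_equal(predict(m2, sweep(X, 2, shift, "+")), predict(m, X),
               tolerance = 1e-10)
})

test_that("NIPALS scores are orthogonal and training error non-increasing", {
  set.seed(34)
  X <- matrix(rnorm(300), 30, 10)
  y <- rnorm(30)
  Xc <- scale(X, scale = FALSE)
  m <- fit_pls(X, y, 6)
  T <- Xc %*% m$W %*% solve(t(m$P) %*% m$W)
  G <- crossprod(T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  rmse_train <- vapply(1:6, function(A)
    sqrt(mean((y - predict(fit_pls(X, y, A), X))^2)), numeric(1))
  expect_true(all(diff(rmse_train) <= 1e-12))
})

test_that("leave-one-out RMSECV equals the hand-enumerated pooled RMSE", {
  # 4 printed points; each fold leaves one out and fits on the other 3
  x <- c(0, 1, 2, 4)
  y <- c(0.1, 1.2, 1.9, 4.2)
  X <- matrix(x)
  preds <- vapply(1:4, function(i) {
    fit <- lm(y[-i] ~ x[-i])
    unname(coef(fit)[1] + coef(fit)[2] * x[i])
  }, numeric(1))
  hand <- sqrt(mean((y - preds)^2))
  cv <- cv_config("kfold", folds = 4, seed = 1, lv_max = 1)
  expect_equal(rmsecv(X, y, 1, cv), hand, tolerance = 1e-10)
})

test_that("RMSECV is deterministic, scale-equivariant, near zero on clean data", {
  set.seed(35)
  t1 <- rnorm(30)
  Xr <- outer(t1, rnorm(12))  # exactly rank 1, y noiseless along it
  yr <- 2.5 * t1
  cvk <- cv_config("kfold", seed = 2, lv_max = 3)
  expect_lt(rmsecv(Xr, yr, 2, cvk), 1e-6)
  cvm <- cv_config("mccv", n_runs = 25, seed = 9, lv_max = 4)
  X <- matrix(rnorm(200), 20, 10); y <- rnorm(20)
  v1 <- rmsecv(X, y, 3, cvm)
  expect_identical(v1, rmsecv(X, y, 3, cvm))
  expect_equal(rmsecv(X, 10 * y, 3, cvm), 10 * v1, tolerance = 1e-10)
})

test_that("PRESS-based LV selection recovers a known factor count", {
  d <- make_factor_data(60, 50, 2, noise_sd = 1e-3, seed = 41)
  r <- select_lv(d$X, d$y, cv_config("mccv", n_runs = 40, seed = 5,
                                     lv_max = 8))
  expect_equal(r$lv, 2)
  expect_length(r$press, 8)
  expect_true(all(r$press >= 0))
  r1 <- select_lv(d$X, d$y, cv_config("kfold", seed = 5, lv_max = 1))
  expect_equal(r1$lv, 1)
})
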
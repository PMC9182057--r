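#' Cross-validation configuration
#'
#' Describes how cross-validated errors (RMSECV, PRESS) are computed: either
#' `kfold` (every sample held out once) or `mccv` (Monte-Carlo CV: repeated
#' random calibration draws of `cal_fraction`, the remainder held out). All
#' randomness is governed by `seed`, so a given configuration always produces
#' the same folds.
#'
#' @param scheme `"kfold"` or `"mccv"`.
#' @param folds number of folds for `kfold` (default 5).
#' @param n_runs number of Monte-Carlo splits for `mccv` (default 100).
#' @param cal_fraction calibration fraction per Monte-Carlo split, in (0, 1)
#'   (default 0.8).
#' @param seed RNG seed for fold assignment.
#' @param lv_max largest latent-variable count considered (default 20).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(scheme = c("mccv", "kfold"), folds = 5L,
                      n_runs = 100L, cal_fraction = 0.8, seed = 1L,
                      lv_max = 20L) {
  scheme <- match.arg(scheme)
  if (cal_fraction <= 0 || cal_fraction >= 1)
    stop("cal_fraction must be in (0, 1)")
  if (lv_max < 1) stop("lv_max must be >= 1")
  if (folds < 2) stop("folds must be >= 2")
  if (n_runs < 1) stop("n_runs must be >= 1")
  structure(list(scheme = scheme, folds = as.integer(folds),
                 n_runs = as.integer(n_runs), cal_fraction = cal_fraction,
                 seed = as.integer(seed), lv_max = as.integer(lv_max)),
            class = "cv_config")
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Column-centers `X` and `y` (no scaling) and extracts `A` latent variables
#' by NIPALS deflation. If the residual covariance collapses before `A`
#' components (rank-deficient data), the model is truncated and the fact is
#' recorded in `$truncated`.
#'
#' @param X predictor matrix (n x p), finite.
#' @param y response vector, length n.
#' @param A number of latent variables, `<= min(n - 1, p)`.
#' @param tol deflation tolerance; a component whose weight or score norm
#'   falls below it ends the extraction.
#' @return An object of class `pls_model` with fields `x_mean`, `y_mean`,
#'   `W`, `P`, `q`, `b` (regression coefficients in centered space), `A`.
#' @examples
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X %*% c(1, -1, 0, 0.5, 0) + 0.01 * rnorm(12)
#' m <- fit_pls(X, y, A = 3)
#' predict(m, X[1:2, ])
#' @export
fit_pls <- function(X, y, A, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples to fit a PLS model")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y")
  A <- as.integer(A)
  A_cap <- min(n - 1L, ncol(X))
  if (A < 1 || A > A_cap)
    stop("A must be in [1, min(n - 1, p)] = [1, ", A_cap, "]")
  f <- .cpp_pls_fit(X, y, A, tol)
  structure(list(x_mean = as.vector(f$x_mean), y_mean = f$y_mean,
                 W = f$W, P = f$P, q = as.vector(f$q), b = as.vector(f$b),
                 A = f$A, A_requested = A, truncated = f$A < A),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model: ", length(x$b), " variables, ", x$A, " latent variables",
      if (x$truncated) paste0(" (truncated from ", x$A_requested, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Predict from a PLS model
#' @param object a [fit_pls()] model.
#' @param newdata matrix with the same column count as the training data.
#' @param ... unused.
#' @return Numeric vector of predictions
#'   `y_mean + (newdata - x_mean) %*% b`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_mean))
  drop(object$y_mean +
         (newdata - rep(object$x_mean, each = nrow(newdata))) %*% object$b)
}

# Fold membership (kfold) or calibration index matrix (mccv), seeded.
.cv_folds <- function(n, cv) {
  with_seed(cv$seed, {
    if (cv$scheme == "kfold") {
      k <- min(cv$folds, n)
      sample(rep_len(seq_len(k), n))
    } else {
      ncal <- max(2L, min(n - 1L, floor(cv$cal_fraction * n)))
      vapply(seq_len(cv$n_runs), function(i) sort(sample.int(n, ncal)),
             integer(ncal))
    }
  })
}

# Pooled held-out squared-error curve over A = 1..lv_max; shared by RMSECV,
# PRESS and LV selection.
.cv_sse_curve <- function(X, y, cv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for cross-validation")
  lv <- .lv_cap(cv$lv_max, n, ncol(X), cv)
  idx <- .cv_folds(n, cv)
  if (cv$scheme == "kfold") {
    r <- .cpp_cv_sse(X, y, as.integer(idx), lv, 1e-10)
  } else {
    r <- .cpp_mccv_sse(X, y, matrix(as.integer(idx), nrow = nrow(idx)),
                       lv, 1e-10)
  }
  list(sse = as.vector(r$sse), n_heldout = r$n_heldout, lv_max = lv)
}

# Largest usable component count given the smallest training-fold size.
.lv_cap <- function(lv_max, n, p, cv) {
  n_train <- if (cv$scheme == "kfold")
    n - ceiling(n / min(cv$folds, n)) else
    max(2L, min(n - 1L, floor(cv$cal_fraction * n)))
  max(1L, min(lv_max, p, n_train - 1L))
}

#' Cross-validated RMSE curve over latent-variable counts
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param cv a [cv_config()].
#' @return Numeric vector `rmsecv[A]` for `A = 1..lv_max` (capped by the data),
#'   pooled over all held-out predictions.
#' @export
rmsecv_curve <- function(X, y, cv = cv_config()) {
  r <- .cv_sse_curve(X, y, cv)
  sqrt(r$sse / r$n_heldout)
}

#' Cross-validated RMSE at a fixed latent-variable count
#'
#' Pooled root mean squared error of the held-out predictions under the given
#' cross-validation scheme; deterministic for a given `cv$seed`.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param A latent-variable count; `NULL` returns the minimum over
#'   `1..cv$lv_max` (the RMSECV at the best component count).
#' @param cv a [cv_config()].
#' @return A single RMSECV value.
#' @export
rmsecv <- function(X, y, A = NULL, cv = cv_config()) {
  curve <- rmsecv_curve(X, y, cv)
  if (is.null(A)) return(min(curve))
  A <- as.integer(A)
  if (A < 1) stop("A must be >= 1")
  curve[min(A, length(curve))]
}

#' Select the number of latent variables by PRESS
#'
#' Computes the prediction residual error sum of squares PRESS(A) for
#' `A = 1..lv_max` under the given cross-validation scheme (Monte-Carlo CV by
#' default) and returns the count with the smallest PRESS; ties go to the
#' smaller count.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param cv a [cv_config()].
#' @return A list with `lv` (the chosen count) and `press` (the full curve).
#' @export
select_lv <- function(X, y, cv = cv_config()) {
  r <- .cv_sse_curve(X, y, cv)
  list(lv = which.min(r$sse), press = r$sse)
}
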
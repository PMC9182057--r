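#' Standard normal variate
#'
#' Row-wise autoscaling of spectra: each spectrum is centered to mean 0 and
#' scaled to unit sample (n-1) standard deviation, removing additive baseline
#' offsets and global intensity differences.
#'
#' @param X absorbance matrix (samples x variables).
#' @return The transformed matrix.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 1, sd)
  if (any(s == 0))
    stop("SNV undefined for constant spectrum (sample ",
         which(s == 0)[1], ")")
  (X - rowMeans(X)) / s
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on a reference spectrum (`x ~ a + b * ref`,
#' ordinary least squares) and corrected to `(x - a) / b`, removing
#' per-sample multiplicative scatter and additive offset. The reference
#' defaults to the column-wise mean of `X`; when correcting validation or
#' test spectra, pass the reference frozen from the calibration set to avoid
#' information leakage.
#'
#' @param X absorbance matrix (samples x variables), `ncol(X) >= 2`.
#' @param reference reference spectrum; default `colMeans(X)`.
#' @param tol slopes with `|b| < tol` are rejected as degenerate.
#' @return The corrected matrix, with the fitted intercepts and slopes in
#'   attributes `"a"` and `"b"`.
#' @export
msc <- function(X, reference = NULL, tol = 1e-10) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("MSC needs at least 2 spectral variables")
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length must equal ncol(X)")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("MSC reference is constant")
  b <- as.vector(X %*% rc) / denom  # least-squares slope; sum(rc) == 0
  if (any(abs(b) < tol))
    stop("MSC slope ~ 0 for sample ", which(abs(b) < tol)[1])
  a <- rowMeans(X) - b * mean(reference)
  out <- (X - a) / b
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

# Savitzky-Golay weight vector: value returned is the deriv-th derivative (in
# index units) of the least-squares polynomial of order `polyorder` fitted to
# ordinates at integer offsets `offsets`, evaluated at offset `at`.
sg_weights <- function(offsets, polyorder, deriv, at = 0) {
  V <- outer(offsets - at, 0:polyorder, `^`)
  G <- solve(crossprod(V), t(V))
  factorial(deriv) * G[deriv + 1, ]
}

#' Savitzky-Golay filtering
#'
#' Row-wise local polynomial smoothing / differentiation. Interior points use
#' the classical convolution weights; at the edges the polynomial is refitted
#' on the truncated window (no padding), so edge variables remain usable by
#' downstream wavelength selection. Derivatives are returned per axis unit:
#' the index-space derivative is divided by `spacing^deriv`.
#'
#' @param X absorbance matrix (samples x variables).
#' @param window odd window width `>= 3`.
#' @param polyorder polynomial order, `< window`.
#' @param deriv derivative order, `<= polyorder`.
#' @param spacing axis step per column (cm^-1); default 1.
#' @return The filtered matrix.
#' @export
savitzky_golay <- function(X, window = 11, polyorder = 2, deriv = 0,
                           spacing = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  if (p < window) stop("spectrum shorter than the filter window")
  h <- (window - 1) %/% 2
  w_mid <- sg_weights(-h:h, polyorder, deriv)
  out <- matrix(0, nrow(X), p)
  # interior: one matrix product per offset
  mid <- (h + 1):(p - h)
  acc <- matrix(0, nrow(X), length(mid))
  for (j in seq_len(window))
    acc <- acc + w_mid[j] * X[, mid + (j - h - 1), drop = FALSE]
  out[, mid] <- acc
  # edges: refit on the truncated window
  for (i in c(seq_len(h), (p - h + 1):p)) {
    win <- max(1, i - h):min(p, i + h)
    ord <- min(polyorder, length(win) - 1)
    if (deriv > ord) { out[, i] <- 0; next }
    w <- sg_weights(win - i, ord, deriv)
    out[, i] <- X[, win, drop = FALSE] %*% w
  }
  out / spacing^deriv
}

#' First derivative of spectra
#'
#' Central differences on the interior, one-sided differences at the ends,
#' with respect to the (possibly non-uniform) wavenumber axis.
#'
#' @param X absorbance matrix.
#' @param axis wavenumber axis, strictly monotonic, length `ncol(X)`.
#' @return Matrix of derivatives, same shape as `X`.
#' @export
first_derivative <- function(X, axis) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 variables for a derivative")
  if (length(axis) != p) stop("axis length must equal ncol(X)")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) stop("axis must be strictly monotonic")
  out <- matrix(0, nrow(X), p)
  out[, 1] <- (X[, 2] - X[, 1]) / (axis[2] - axis[1])
  out[, p] <- (X[, p] - X[, p - 1]) / (axis[p] - axis[p - 1])
  if (p > 2) {
    i <- 2:(p - 1)
    out[, i] <- (X[, i + 1, drop = FALSE] - X[, i - 1, drop = FALSE]) /
      rep(axis[i + 1] - axis[i - 1], each = nrow(X))
  }
  out
}

#' Vector normalization
#'
#' Scales each spectrum to unit Euclidean norm.
#' @param X absorbance matrix.
#' @return The normalized matrix.
#' @export
normalize_rows <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("cannot normalize an all-zero spectrum")
  X / nrm
}

.pp_step_names <- c("sg", "msc", "snv", "fd", "norm")

#' Define a preprocessing pipeline
#'
#' A `preprocess_spec` is an ordered list of pretreatment steps from the set
#' `sg` (Savitzky-Golay), `msc`, `snv`, `fd` (first derivative), `norm`
#' (vector normalization). Steps are applied left to right.
#'
#' @param ... step names as character strings, or lists like
#'   `list(name = "sg", window = 11, polyorder = 2, deriv = 0)` to override
#'   Savitzky-Golay parameters.
#' @return An object of class `preprocess_spec`.
#' @examples
#' preprocess_spec("sg", "msc")
#' preprocess_spec(list(name = "sg", window = 7, polyorder = 3, deriv = 1))
#' @export
preprocess_spec <- function(...) {
  steps <- lapply(list(...), function(s) {
    if (is.character(s)) s <- list(name = s)
    if (is.null(s$name) || !s$name %in% .pp_step_names)
      stop("unknown preprocessing step: ",
           if (is.null(s$name)) "<unnamed>" else s$name)
    if (s$name == "sg") {
      s$window <- if (is.null(s$window)) 11L else as.integer(s$window)
      s$polyorder <- if (is.null(s$polyorder)) 2L else as.integer(s$polyorder)
      s$deriv <- if (is.null(s$deriv)) 0L else as.integer(s$deriv)
      if (s$window < 3 || s$window %% 2 == 0) stop("sg window must be odd >= 3")
      if (s$polyorder >= s$window) stop("sg polyorder must be < window")
      if (s$deriv < 0 || s$deriv > s$polyorder)
        stop("sg deriv must be in [0, polyorder]")
    }
    s
  })
  structure(list(steps = steps), class = "preprocess_spec")
}

#' @export
format.preprocess_spec <- function(x, ...) {
  if (length(x$steps) == 0) return("raw")
  paste(vapply(x$steps, function(s) {
    if (s$name == "sg")
      sprintf("sg(%d,%d,%d)", s$window, s$polyorder, s$deriv)
    else s$name
  }, ""), collapse = "+")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("preprocess_spec:", format(x), "\n")
  invisible(x)
}

#' Fit a preprocessing pipeline on calibration spectra
#'
#' Learns the data-dependent statistics of a [preprocess_spec()] (currently
#' the MSC reference spectrum, taken as the mean of the calibration spectra at
#' the point in the pipeline where the MSC step runs) so the identical
#' transform can later be applied to validation or test spectra without
#' leakage.
#'
#' @param X calibration absorbance matrix.
#' @param spec a [preprocess_spec()].
#' @param axis wavenumber axis (needed by `fd` and for the `sg` derivative
#'   scale).
#' @return An object of class `preprocess_fit`; apply it with
#'   [preprocess_apply()].
#' @export
preprocess_fit <- function(X, spec, axis = seq_len(ncol(X))) {
  stopifnot(inherits(spec, "preprocess_spec"))
  X <- as.matrix(X)
  refs <- vector("list", length(spec$steps))
  cur <- X
  for (i in seq_along(spec$steps)) {
    s <- spec$steps[[i]]
    if (s$name == "msc") refs[[i]] <- colMeans(cur)
    cur <- .pp_apply_step(cur, s, axis, refs[[i]])
  }
  structure(list(spec = spec, axis = axis, msc_refs = refs),
            class = "preprocess_fit")
}

.pp_apply_step <- function(X, s, axis, msc_ref = NULL) {
  switch(s$name,
    sg = savitzky_golay(X, s$window, s$polyorder, s$deriv,
                        spacing = mean(abs(diff(axis)))),
    msc = msc(X, reference = msc_ref),
    snv = snv(X),
    fd = first_derivative(X, axis),
    norm = normalize_rows(X))
}

#' Apply a fitted preprocessing pipeline
#' @param fit a [preprocess_fit()].
#' @param X absorbance matrix with the same variable count the fit was
#'   trained on.
#' @return The transformed matrix.
#' @export
preprocess_apply <- function(fit, X) {
  stopifnot(inherits(fit, "preprocess_fit"))
  X <- as.matrix(X)
  for (i in seq_along(fit$spec$steps))
    X <- .pp_apply_step(X, fit$spec$steps[[i]], fit$axis, fit$msc_refs[[i]])
  X
}

#' Default pretreatment candidate grid
#'
#' Raw spectra, the five single pretreatments, and every ordered pair of
#' distinct pretreatments (26 candidates in total).
#'
#' @param sg_window,sg_polyorder,sg_deriv Savitzky-Golay parameters used for
#'   every `sg` step in the grid.
#' @return A list of [preprocess_spec()] objects.
#' @export
default_preprocess_candidates <- function(sg_window = 11, sg_polyorder = 2,
                                          sg_deriv = 0) {
  mk <- function(nm) {
    if (nm == "sg") list(name = "sg", window = sg_window,
                         polyorder = sg_polyorder, deriv = sg_deriv)
    else list(name = nm)
  }
  out <- list(preprocess_spec())
  for (a in .pp_step_names) out <- c(out, list(preprocess_spec(mk(a))))
  for (a in .pp_step_names) for (b in setdiff(.pp_step_names, a))
    out <- c(out, list(preprocess_spec(mk(a), mk(b))))
  out
}

#' Choose a pretreatment by minimum RMSECV
#'
#' Applies each candidate pipeline to the spectra, cross-validates a PLS model
#' for the analyte, and returns the candidate with the smallest RMSECV (at its
#' best latent-variable count up to `cv$lv_max`). Ties keep the earliest
#' candidate; candidates that fail on the data (e.g. SNV on a constant
#' spectrum) are recorded as failed rather than aborting the search.
#'
#' @param ds a [spectra_dataset()].
#' @param analyte analyte name in `ds$y`.
#' @param candidates list of [preprocess_spec()]; default
#'   [default_preprocess_candidates()].
#' @param cv a [cv_config()].
#' @return A list with `best` (the winning `preprocess_spec`) and `table`
#'   (data.frame: candidate, rmsecv, lv, status).
#' @export
select_preprocessing <- function(ds, analyte,
                                 candidates = default_preprocess_candidates(),
                                 cv = cv_config()) {
  stopifnot(inherits(ds, "spectra_dataset"), length(candidates) >= 1)
  y <- .get_analyte(ds, analyte)
  rows <- lapply(candidates, function(sp) {
    res <- tryCatch({
      fit <- preprocess_fit(ds$X, sp, ds$axis)
      Xp <- preprocess_apply(fit, ds$X)
      curve <- rmsecv_curve(Xp, y, cv)
      list(rmsecv = min(curve), lv = which.min(curve), status = "ok")
    }, error = function(e) list(rmsecv = NA_real_, lv = NA_integer_,
                                status = conditionMessage(e)))
    data.frame(candidate = format(sp), rmsecv = res$rmsecv, lv = res$lv,
               status = res$status, stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  if (all(is.na(table$rmsecv))) stop("every preprocessing candidate failed")
  best_i <- which.min(table$rmsecv)  # which.min: first index on ties
  list(best = candidates[[best_i]], best_index = best_i, table = table)
}

.get_analyte <- function(ds, analyte) {
  if (!analyte %in% names(ds$y))
    stop("unknown analyte '", analyte, "'; available: ",
         paste(names(ds$y), collapse = ", "))
  ds$y[[analyte]]
}
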
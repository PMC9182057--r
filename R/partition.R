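#' Random independent-test-set draw
#'
#' Uniform draw of `k` sample ids without replacement, deterministic for a
#' given seed; the order of the remaining ids is preserved.
#'
#' @param ids vector of sample identifiers.
#' @param k number of ids to draw, `0 < k < length(ids)`.
#' @param seed RNG seed.
#' @return A list with `itest_ids` and `remaining_ids`.
#' @export
random_itest <- function(ids, k, seed = 1L) {
  n <- length(ids)
  if (k <= 0 || k >= n) stop("k must satisfy 0 < k < ", n)
  pick <- with_seed(seed, sort(sample.int(n, k)))
  list(itest_ids = ids[pick], remaining_ids = ids[-pick])
}

#' SPXY calibration/validation split
#'
#' Sample-set partitioning based on joint x-y distances: pairwise distances
#' are `d(p, q) = d_x(p, q) / max(d_x) + d_y(p, q) / max(d_y)` with Euclidean
#' `d_x` on the spectra and `|y_p - y_q|` on the reference values. The two
#' most distant samples seed the calibration set, then the sample with the
#' largest minimum distance to the current calibration set is added until
#' `n_cal` samples are selected; the rest form the validation set. Fully
#' deterministic; ties are broken by the lowest original row index.
#'
#' @param X spectra matrix (rows = samples), normally the preprocessed
#'   spectra used for modeling.
#' @param y reference values, length `nrow(X)`.
#' @param n_cal calibration-set size, `2 <= n_cal < nrow(X)`.
#' @return A list of class `split_assignment` with `cal_idx`, `val_idx`
#'   (1-based row indices) and `n_cal`.
#' @export
spxy_split <- function(X, y, n_cal) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n_cal < 2 || n_cal >= n) stop("n_cal must satisfy 2 <= n_cal < ", n)
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, `-`))
  mx <- max(dx); my <- max(dy)
  if (mx == 0) stop("all spectra identical: SPXY x-distance degenerate")
  d <- dx / mx + if (my > 0) dy / my else 0
  # seed pair: global maximum distance, lowest indices on ties
  flat <- which(d == max(d), arr.ind = TRUE)
  flat <- flat[order(pmin(flat[, 1], flat[, 2]),
                     pmax(flat[, 1], flat[, 2])), , drop = FALSE]
  sel <- sort(unique(as.integer(flat[1, ])))
  mind <- unname(pmin(d[, sel[1]], d[, sel[2]]))
  while (length(sel) < n_cal) {
    mind[sel] <- -Inf
    nxt <- as.integer(which.max(mind))  # lowest index wins ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, unname(d[, nxt]))
  }
  sel <- sort(sel)
  structure(list(cal_idx = sel, val_idx = setdiff(seq_len(n), sel),
                 n_cal = as.integer(n_cal)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("split_assignment: ", length(x$cal_idx), " calibration / ",
      length(x$val_idx), " validation samples\n", sep = "")
  invisible(x)
}
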
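#' Backward interval PLS wavelength selection
#'
#' Splits the spectrum into `n_intervals` contiguous, (near-)equal-width
#' blocks and eliminates them backwards: at every step the interval whose
#' removal yields the smallest cross-validated RMSE of a PLS model on the
#' remaining intervals is dropped, recording the RMSECV after each
#' elimination, until a single interval remains. The returned subset is the
#' interval combination with the global minimum RMSECV over the whole trace
#' (including the un-eliminated start).
#'
#' Interval widths: each block has `floor(p / n)` variables and the remainder
#' is distributed one per interval starting from the first.
#'
#' @param ds a [spectra_dataset()].
#' @param analyte analyte name.
#' @param n_intervals number of sub-intervals, `<= ncol(ds$X)`.
#' @param cv a [cv_config()]; a deterministic scheme (`kfold`) keeps the
#'   whole procedure deterministic.
#' @return A [selection_result()]; `details$intervals` holds the interval
#'   index blocks, `details$kept_intervals` the winning combination, and
#'   `trace` a data.frame with one row per elimination level.
#' @export
bipls <- function(ds, analyte, n_intervals, cv = cv_config(scheme = "kfold")) {
  stopifnot(inherits(ds, "spectra_dataset"))
  y <- .get_analyte(ds, analyte)
  p <- ncol(ds$X)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  if (n_intervals > p) stop("n_intervals (", n_intervals,
                            ") exceeds variable count (", p, ")")
  intervals <- .make_intervals(p, n_intervals)
  fcv <- .fitness_cv(cv)

  alive <- seq_len(n_intervals)
  f0 <- .subset_fitness(ds$X, y, unlist(intervals[alive]), fcv)
  trace <- data.frame(step = 0L, n_remaining = n_intervals,
                      removed = NA_integer_, rmsecv = f0$rmsecv,
                      lv = f0$lv)
  best <- list(alive = alive, rmsecv = f0$rmsecv, lv = f0$lv)
  step <- 0L
  while (length(alive) > 1) {
    step <- step + 1L
    cand <- vapply(seq_along(alive), function(j) {
      keep <- alive[-j]
      .subset_fitness(ds$X, y, unlist(intervals[keep]), fcv)$rmsecv
    }, numeric(1))
    j <- which.min(cand)  # lowest interval index on ties
    removed <- alive[j]
    alive <- alive[-j]
    f <- .subset_fitness(ds$X, y, unlist(intervals[alive]), fcv)
    trace <- rbind(trace, data.frame(step = step,
                                     n_remaining = length(alive),
                                     removed = removed, rmsecv = f$rmsecv,
                                     lv = f$lv))
    if (f$rmsecv < best$rmsecv)
      best <- list(alive = alive, rmsecv = f$rmsecv, lv = f$lv)
  }
  selection_result(unlist(intervals[best$alive]), "bipls",
                   rmsecv = best$rmsecv, cv = fcv, lv = best$lv,
                   trace = trace,
                   details = list(n_intervals = n_intervals,
                                  intervals = intervals,
                                  kept_intervals = best$alive))
}

# Contiguous index blocks: floor(p/n) each, remainder spread from the first.
.make_intervals <- function(p, n) {
  base <- p %/% n
  rem <- p %% n
  sizes <- rep(base, n) + c(rep(1L, rem), rep(0L, n - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  lapply(seq_len(n), function(i) starts[i]:ends[i])
}

#' Scan interval counts for BIPLS
#'
#' Runs [bipls()] for each interval count in `n_list` and picks the count
#' with the smallest RMSECV. With `refine = TRUE` the integer bracket between
#' the best and second-best coarse counts is then scanned exhaustively and
#' the refined optimum returned.
#'
#' @param ds a [spectra_dataset()].
#' @param analyte analyte name.
#' @param n_list integer vector of interval counts to try.
#' @param refine scan the bracket between the two best coarse counts
#'   (default `TRUE`).
#' @param cv a [cv_config()].
#' @return A list: `best_n`, `best_result` (a [selection_result()]), and
#'   `table` (one row per count tried: `n`, `n_selected_intervals`,
#'   `rmsecv`, `n_wavelengths`).
#' @export
bipls_scan <- function(ds, analyte, n_list, refine = TRUE,
                       cv = cv_config(scheme = "kfold")) {
  n_list <- unique(as.integer(n_list))
  if (length(n_list) < 1) stop("n_list must be nonempty")
  run_one <- function(n) {
    r <- bipls(ds, analyte, n, cv = cv)
    list(result = r,
         row = data.frame(n = n,
                          n_selected_intervals =
                            length(r$details$kept_intervals),
                          rmsecv = r$rmsecv,
                          n_wavelengths = length(r$subset)))
  }
  runs <- lapply(n_list, run_one)
  table <- do.call(rbind, lapply(runs, `[[`, "row"))
  if (refine && length(n_list) >= 2) {
    ord <- order(table$rmsecv)
    lo <- min(table$n[ord[1:2]]); hi <- max(table$n[ord[1:2]])
    extra <- setdiff(seq(lo, hi), table$n)
    if (length(extra)) {
      more <- lapply(extra, run_one)
      runs <- c(runs, more)
      table <- rbind(table, do.call(rbind, lapply(more, `[[`, "row")))
    }
  }
  best_i <- which.min(table$rmsecv)
  list(best_n = table$n[best_i], best_result = runs[[best_i]]$result,
       table = table)
}
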
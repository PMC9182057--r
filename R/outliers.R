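#' MCCV residual statistics for abnormal-sample screening
#'
#' Runs Monte-Carlo cross-validation: in each run a random calibration
#' fraction is drawn, a PLS model is fitted on it, and the held-out samples
#' are predicted. Signed residuals `y - yhat` are accumulated per sample and
#' summarized as a per-sample residual mean and variance; samples with a
#' large residual mean (systematic misfit) or variance (unstable prediction)
#' are candidate outliers.
#'
#' By default the reported mean is the mean of `|residual|`, matching the
#' non-negative residual-mean axis used in screening maps; set
#' `mean_type = "signed"` for the raw signed mean. The variance is the sample
#' variance of the signed residuals.
#'
#' @param ds a [spectra_dataset()].
#' @param analyte analyte name in `ds$y`.
#' @param n_runs number of MCCV runs (default 1000).
#' @param cal_fraction calibration fraction per run (default 0.75).
#' @param A latent-variable count; `NULL` (default) selects it once on the
#'   full data via [select_lv()] and keeps it fixed across runs.
#' @param seed RNG seed.
#' @param mean_type `"absolute"` (default) or `"signed"`.
#' @param cv a [cv_config()] used only when `A` is `NULL`.
#' @return A data.frame of class `residual_stats`: `id`, `n_heldout`,
#'   `res_mean`, `res_var`.
#' @export
mccv_residual_stats <- function(ds, analyte, n_runs = 1000L,
                                cal_fraction = 0.75, A = NULL, seed = 1L,
                                mean_type = c("absolute", "signed"),
                                cv = cv_config(seed = seed)) {
  stopifnot(inherits(ds, "spectra_dataset"))
  mean_type <- match.arg(mean_type)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (cal_fraction <= 0 || cal_fraction >= 1)
    stop("cal_fraction must be in (0, 1)")
  y <- .get_analyte(ds, analyte)
  n <- nrow(ds$X)
  if (is.null(A)) A <- select_lv(ds$X, y, cv)$lv
  ncal <- max(2L, min(n - 1L, floor(cal_fraction * n)))
  calmat <- with_seed(seed, vapply(seq_len(n_runs), function(i)
    sort(sample.int(n, ncal)), integer(ncal)))
  r <- .cpp_mccv_residuals(ds$X, y, matrix(as.integer(calmat), nrow = ncal),
                           as.integer(min(A, ncal - 1L)), 1e-10)
  cnt <- r$count
  if (any(cnt < 1))
    stop("sample(s) never held out after ", n_runs,
         " runs (e.g. '", ds$ids[which(cnt < 1)[1]],
         "'); increase n_runs")
  res_mean <- if (mean_type == "absolute") r$sum_abs / cnt else r$sum / cnt
  res_var <- ifelse(cnt > 1,
                    (r$sum_sq - r$sum^2 / cnt) / (cnt - 1), 0)
  res_var <- pmax(res_var, 0)  # guard tiny negative rounding
  out <- data.frame(id = ds$ids, n_heldout = as.integer(cnt),
                    res_mean = res_mean, res_var = res_var,
                    stringsAsFactors = FALSE)
  class(out) <- c("residual_stats", "data.frame")
  attr(out, "A") <- A
  attr(out, "mean_type") <- mean_type
  out
}

#' Flag abnormal samples from MCCV residual statistics
#'
#' A sample is flagged when its residual mean is strictly greater than
#' `mean_threshold` OR its residual variance is strictly greater than
#' `var_threshold`. The defaults (2.5 on the residual-mean scale, 0.3 on the
#' variance scale, both in squared/plain units of the analyte %) are the
#' conventional screening thresholds for stover constituent calibrations;
#' they should be rescaled for analytes on a different scale.
#'
#' @param stats a [mccv_residual_stats()] data.frame.
#' @param mean_threshold positive threshold on the residual mean.
#' @param var_threshold positive threshold on the residual variance.
#' @return Sorted integer vector of flagged row indices (possibly empty),
#'   with the matching ids as names.
#' @export
flag_outliers <- function(stats, mean_threshold = 2.5, var_threshold = 0.3) {
  stopifnot(is.data.frame(stats),
            all(c("res_mean", "res_var") %in% names(stats)))
  if (mean_threshold <= 0 || var_threshold <= 0)
    stop("thresholds must be positive")
  idx <- sort(which(stats$res_mean > mean_threshold |
                      stats$res_var > var_threshold))
  stats::setNames(idx, stats$id[idx])
}
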
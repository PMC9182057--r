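#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Can be negative for
#' models worse than the mean.
#'
#' @param y measured values.
#' @param y_hat predicted values, same length.
#' @return R-squared.
#' @export
r2 <- function(y, y_hat) {
  .check_pair(y, y_hat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R^2 undefined: measured values are constant")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Root mean squared error
#'
#' `RMSE = sqrt(sum((y - yhat)^2) / n)` (population denominator `n`).
#'
#' @inheritParams r2
#' @return RMSE, in the units of `y`.
#' @export
rmse <- function(y, y_hat) {
  .check_pair(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

#' Residual predictive deviation
#'
#' `RPD = sqrt(sum((y - mean(y))^2) / sum((y - yhat)^2))`, i.e. the
#' population standard deviation of the measured values divided by the RMSE.
#' RPD >= 3 is conventionally taken as a usable calibration. A perfect
#' prediction yields `Inf` (returned, not raised).
#'
#' @inheritParams r2
#' @return RPD (dimensionless); `Inf` for an exact fit.
#' @export
rpd <- function(y, y_hat) {
  .check_pair(y, y_hat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("RPD undefined: measured values are constant")
  ss_res <- sum((y - y_hat)^2)
  if (ss_res == 0) return(Inf)
  sqrt(ss_tot / ss_res)
}

#' Relative RMSE in percent
#'
#' `100 * rmse / y_bar`; models with relative RMSE below 5% are conventionally
#' considered adequate for routine constituent analysis.
#'
#' @param rmse_value an RMSE.
#' @param y_bar mean of the measured values (nonzero).
#' @return Percent value.
#' @export
relative_rmse <- function(rmse_value, y_bar) {
  if (y_bar == 0) stop("relative RMSE undefined for zero mean")
  100 * rmse_value / y_bar
}

#' Percent change from a reference value
#'
#' `100 * (old - new) / old`: positive when `new` is smaller (a reduction).
#'
#' @param old reference value (nonzero).
#' @param new comparison value.
#' @return Percent change.
#' @export
percent_change <- function(old, new) {
  if (old == 0) stop("percent change undefined for zero reference")
  100 * (old - new) / old
}

.check_pair <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stop("y and y_hat must have equal length")
  if (length(y) < 1) stop("empty input")
  invisible(TRUE)
}

#' Evaluate a model variant on calibration / validation / test splits
#'
#' Builds one evaluation row per split with R^2, RMSE, RPD and relative RMSE,
#' plus the model-complexity columns (latent variables, wavelength count and
#' its fraction of the full spectrum).
#'
#' @param splits named list of `list(y = , y_hat = )` pairs, e.g.
#'   `list(Cset = ..., Vset = ...)`.
#' @param model_name label for the variant (e.g. `"Full-PLS"`).
#' @param n_wavelengths number of wavelength variables in the model.
#' @param n_full number of wavelength variables in the full spectrum.
#' @param lv latent-variable count.
#' @return A data.frame with one row per split.
#' @export
evaluation_report <- function(splits, model_name, n_wavelengths, n_full,
                              lv) {
  rows <- lapply(names(splits), function(nm) {
    s <- splits[[nm]]
    rm <- rmse(s$y, s$y_hat)
    data.frame(model = model_name, split = nm,
               nw = as.integer(n_wavelengths),
               nw_fraction_pct = 100 * n_wavelengths / n_full,
               lv = as.integer(lv),
               r2 = r2(s$y, s$y_hat), rmse = rm,
               rpd = rpd(s$y, s$y_hat),
               rel_rmse_pct = relative_rmse(rm, mean(s$y)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
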
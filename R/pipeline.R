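#' Run the end-to-end calibration workflow
#'
#' Orchestrates the full modeling pipeline for each requested analyte:
#' pretreatment (fixed or chosen by minimum RMSECV), MCCV abnormal-sample
#' screening, independent-test-set draw, SPXY calibration/validation
#' splitting, wavelength selection, latent-variable selection by MCCV/PRESS,
#' final PLS fits and evaluation on all three splits.
#'
#' Two stage orders are available. `"strict"` (default) draws the
#' independent test set first and fits every data-dependent statistic
#' (pretreatment choice, MSC reference, centering, screening, selection)
#' without it, so test rows can never leak into the model. `"screen_first"`
#' screens abnormal samples on the full data and draws the test set
#' afterwards, the traditional ordering for published stover calibrations.
#' In both orders the final pretreatment statistics are refit on the
#' calibration set only.
#'
#' @param ds a [spectra_dataset()]; alternatively pass `synthetic`.
#' @param synthetic a [synthetic_spec()] used (with `seed`) when `ds` is
#'   missing.
#' @param analytes analyte names to model (default: all in the dataset).
#' @param selectors any of `"full"`, `"bipls"`, `"cars"`, `"bipls-cars"`,
#'   `"bipls-gsa"`, `"cars-gsa"`.
#' @param preprocess a [preprocess_spec()], or `"auto"` to choose by minimum
#'   RMSECV over `pp_candidates`.
#' @param pp_candidates candidate list for `"auto"` (default
#'   [default_preprocess_candidates()]).
#' @param itest_k independent-test-set size (rounded fraction of the sample
#'   count if < 1; default 0.25).
#' @param cal_ratio calibration share of the SPXY split (default 2/3).
#' @param screen_runs,mean_threshold,var_threshold MCCV screening settings
#'   (see [mccv_residual_stats()], [flag_outliers()]); `screen_runs = 0`
#'   disables screening.
#' @param bipls_n_intervals interval count(s) for BIPLS stages.
#' @param cars_cfg a [cars_config()].
#' @param gsa_cfg a [gsa_config()].
#' @param cv a [cv_config()] for selector fitness and RMSECV tables.
#' @param final_cv a [cv_config()] for final latent-variable selection
#'   (default MCCV, 100 runs, 80 % calibration).
#' @param order `"strict"` or `"screen_first"` (see Details).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory for artifacts (report CSV, selection
#'   JSONs, screening CSV, split JSON).
#' @return A list of class `pipeline_result`: `report` (one evaluation row
#'   per model/split/analyte), `selections`, `splits`, `screening`,
#'   `preprocess`, `config`.
#' @export
run_pipeline <- function(ds = NULL, synthetic = NULL,
                         analytes = NULL,
                         selectors = c("full", "bipls", "cars",
                                       "bipls-cars", "bipls-gsa",
                                       "cars-gsa"),
                         preprocess = "auto",
                         pp_candidates = default_preprocess_candidates(),
                         itest_k = 0.25, cal_ratio = 2 / 3,
                         screen_runs = 300L, mean_threshold = 2.5,
                         var_threshold = 0.3,
                         bipls_n_intervals = 20L,
                         cars_cfg = cars_config(),
                         gsa_cfg = gsa_config(),
                         cv = cv_config(scheme = "kfold"),
                         final_cv = cv_config(scheme = "mccv"),
                         order = c("strict", "screen_first"),
                         seed = 1L, out_dir = NULL) {
  order <- match.arg(order)
  selectors <- match.arg(selectors, several.ok = TRUE)
  if (is.null(ds)) {
    if (is.null(synthetic)) stop("provide either `ds` or `synthetic`")
    ds <- generate_spectra(synthetic, seed = derive_seed(seed, 1L))$dataset
  }
  if (is.null(analytes)) analytes <- names(ds$y)
  if (length(analytes) == 0) stop("dataset has no analytes to model")
  n <- nrow(ds$X)
  k_itest <- if (itest_k < 1) max(1L, round(itest_k * n)) else
    as.integer(itest_k)

  out <- list(report = NULL, selections = list(), splits = list(),
              screening = list(), preprocess = list(),
              config = list(order = order, seed = seed,
                            selectors = selectors, itest_k = k_itest,
                            cal_ratio = cal_ratio))
  for (ai in seq_along(analytes)) {
    an <- analytes[[ai]]
    res <- .pipeline_one(ds, an, selectors, preprocess, pp_candidates,
                         k_itest, cal_ratio, screen_runs, mean_threshold,
                         var_threshold, bipls_n_intervals, cars_cfg,
                         gsa_cfg, cv, final_cv, order,
                         seed = derive_seed(seed, 1000L + ai))
    out$report <- rbind(out$report, res$report)
    out$selections[[an]] <- res$selections
    out$splits[[an]] <- res$split
    out$screening[[an]] <- res$screening
    out$preprocess[[an]] <- res$preprocess
  }
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) .write_artifacts(out, out_dir)
  out
}

.pipeline_one <- function(ds, analyte, selectors, preprocess, pp_candidates,
                          k_itest, cal_ratio, screen_runs, mean_threshold,
                          var_threshold, bipls_n_intervals, cars_cfg,
                          gsa_cfg, cv, final_cv, order, seed) {
  n <- nrow(ds$X)
  if (order == "strict") {
    it <- random_itest(ds$ids, k_itest, seed = derive_seed(seed, 1L))
    pool <- subset_samples(ds, it$remaining_ids)
    itest <- subset_samples(ds, it$itest_ids)
  } else {
    pool <- ds
    itest <- NULL
  }

  # pretreatment choice on the working pool
  pp_spec <- if (inherits(preprocess, "preprocess_spec")) preprocess else
    select_preprocessing(pool, analyte, pp_candidates,
                         cv = .fitness_cv(cv))$best
  pool_fit <- preprocess_fit(pool$X, pp_spec, pool$axis)
  pool_X <- preprocess_apply(pool_fit, pool$X)

  # MCCV abnormal-sample screening on the pool
  screening <- NULL
  if (screen_runs > 0) {
    pool_pp <- spectra_dataset(pool$axis, pool_X, pool$y, pool$ids)
    stats <- mccv_residual_stats(pool_pp, analyte, n_runs = screen_runs,
                                 seed = derive_seed(seed, 2L),
                                 cv = .fitness_cv(cv))
    flagged <- flag_outliers(stats, mean_threshold, var_threshold)
    screening <- list(stats = stats, flagged = flagged)
    if (length(flagged)) {
      keep <- setdiff(seq_len(nrow(pool$X)), flagged)
      pool <- subset_samples(pool, keep)
      pool_X <- pool_X[keep, , drop = FALSE]
    }
  }

  if (order == "screen_first") {
    it <- random_itest(pool$ids, k_itest, seed = derive_seed(seed, 1L))
    itest <- subset_samples(pool, match(it$itest_ids, pool$ids))
    keep <- match(it$remaining_ids, pool$ids)
    pool <- subset_samples(pool, keep)
    pool_X <- pool_X[keep, , drop = FALSE]
  }

  if (nrow(pool$X) < 6)
    stop("only ", nrow(pool$X), " samples left after test-set withdrawal ",
         "and abnormal-sample screening; need at least 6 to split and model")

  # SPXY split on the preprocessed pool
  y_pool <- .get_analyte(pool, analyte)
  n_cal <- max(2L, round(cal_ratio * nrow(pool$X)))
  split <- spxy_split(pool_X, y_pool, n_cal)
  cal <- subset_samples(pool, split$cal_idx)
  val <- subset_samples(pool, split$val_idx)

  # final pretreatment statistics from the calibration set only
  cal_fit <- preprocess_fit(cal$X, pp_spec, cal$axis)
  Xc <- preprocess_apply(cal_fit, cal$X)
  Xv <- preprocess_apply(cal_fit, val$X)
  Xt <- if (!is.null(itest)) preprocess_apply(cal_fit, itest$X) else NULL
  cal_pp <- spectra_dataset(cal$axis, Xc, cal$y, cal$ids)
  yc <- .get_analyte(cal, analyte)
  yv <- .get_analyte(val, analyte)
  yt <- if (!is.null(itest)) .get_analyte(itest, analyte) else NULL
  p_full <- ncol(Xc)

  run_selector <- function(sel, sseed) {
    switch(sel,
      "full" = NULL,
      "bipls" = if (length(bipls_n_intervals) > 1)
        bipls_scan(cal_pp, analyte, bipls_n_intervals, cv = cv)$best_result
      else bipls(cal_pp, analyte, bipls_n_intervals, cv = cv),
      "cars" = cars_repeat(cal_pp, analyte, cars_cfg, seed = sseed),
      "bipls-cars" = chain_select(cal_pp, analyte, "bipls", "cars",
                                  bipls_n_intervals, cars_cfg, gsa_cfg,
                                  cv, seed = sseed),
      "bipls-gsa" = chain_select(cal_pp, analyte, "bipls", "gsa",
                                 bipls_n_intervals, cars_cfg, gsa_cfg,
                                 cv, seed = sseed),
      "cars-gsa" = chain_select(cal_pp, analyte, "cars", "gsa",
                                bipls_n_intervals, cars_cfg, gsa_cfg,
                                cv, seed = sseed))
  }
  model_label <- c("full" = "Full-PLS", "bipls" = "BIPLS", "cars" = "CARS",
                   "bipls-cars" = "BIPLS-CARS", "bipls-gsa" = "BIPLS-GSA",
                   "cars-gsa" = "CARS-GSA")

  report <- NULL
  selections <- list()
  for (si in seq_along(selectors)) {
    sel <- selectors[[si]]
    selres <- run_selector(sel, derive_seed(seed, 10L + si))
    idx <- if (is.null(selres)) seq_len(p_full) else selres$subset
    fin_cv <- final_cv
    fin_cv$seed <- derive_seed(seed, 50L + si)
    lv <- select_lv(Xc[, idx, drop = FALSE], yc, fin_cv)$lv
    m <- fit_pls(Xc[, idx, drop = FALSE], yc, lv)
    splits <- list(
      Cset = list(y = yc, y_hat = predict(m, Xc[, idx, drop = FALSE])),
      Vset = list(y = yv, y_hat = predict(m, Xv[, idx, drop = FALSE])))
    if (!is.null(Xt))
      splits$ITset <- list(y = yt,
                           y_hat = predict(m, Xt[, idx, drop = FALSE]))
    rows <- evaluation_report(splits, model_label[[sel]], length(idx),
                              p_full, m$A)
    rows$analyte <- analyte
    report <- rbind(report, rows)
    if (!is.null(selres)) selections[[sel]] <- selres
  }
  list(report = report, selections = selections, split = split,
       screening = screening,
       preprocess = list(spec = pp_spec, label = format(pp_spec)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (seed ", x$config$seed, ", order ",
      x$config$order, ")\n", sep = "")
  print(x$report, digits = 4)
  invisible(x)
}

.write_artifacts <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(out$report, file.path(out_dir, "report.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  for (an in names(out$selections)) {
    for (sel in names(out$selections[[an]]))
      write_selection_json(out$selections[[an]][[sel]],
                           file.path(out_dir,
                                     paste0("selection_", an, "_", sel,
                                            ".json")))
    sp <- out$splits[[an]]
    jsonlite::write_json(list(cal_idx = sp$cal_idx, val_idx = sp$val_idx),
                         file.path(out_dir, paste0("split_", an, ".json")),
                         auto_unbox = TRUE)
    if (!is.null(out$screening[[an]])) {
      st <- out$screening[[an]]$stats
      st$flagged <- seq_len(nrow(st)) %in% out$screening[[an]]$flagged
      write.table(st,
                  file.path(out_dir, paste0("screening_", an, ".csv")),
                  sep = ",", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out_dir)
}

#' Compare model variants against the full-spectrum baseline
#'
#' Adds the derived comparison quantities to a pipeline report: percent
#' reduction of the validation RMSE versus the full-spectrum model, the RPD
#' gain, and each variant's share of the full spectrum.
#'
#' @param report the `report` data.frame of a [run_pipeline()] result (or
#'   the result itself).
#' @param split which split to compare on (default `"Vset"`).
#' @return A data.frame with one row per analyte and model:
#'   `nw`, `nw_fraction_pct`, `rmsep`, `rmsep_reduction_pct`, `rpd`,
#'   `rpd_delta`.
#' @export
compare_report <- function(report, split = "Vset") {
  if (inherits(report, "pipeline_result")) report <- report$report
  rows <- report[report$split == split, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows for split '", split, "'")
  out <- NULL
  for (an in unique(rows$analyte)) {
    r <- rows[rows$analyte == an, , drop = FALSE]
    full <- r[r$model == "Full-PLS", , drop = FALSE]
    if (nrow(full) != 1)
      stop("analyte '", an, "': need exactly one Full-PLS row to compare")
    if (nrow(r) < 2)
      stop("analyte '", an, "': need at least 2 model rows to compare")
    out <- rbind(out, data.frame(
      analyte = an, model = r$model, nw = r$nw,
      nw_fraction_pct = r$nw_fraction_pct, rmsep = r$rmse,
      rmsep_reduction_pct = vapply(r$rmse, function(v)
        percent_change(full$rmse, v), numeric(1)),
      rpd = r$rpd, rpd_delta = r$rpd - full$rpd,
      stringsAsFactors = FALSE))
  }
  out
}
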
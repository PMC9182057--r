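#' Benchmark the wavelength selectors against the full spectrum
#'
#' Runs the package's reference simulation study: for each seed, a
#' corn-stover-like dataset is generated, Savitzky-Golay smoothed, split
#' 2:1 by SPXY, all requested selectors are run on the calibration set, a
#' final PLS model per variant is built with its latent-variable count
#' chosen by MCCV/PRESS, and the validation-set RMSEP is recorded. For the
#' CARS-GSA chain the recovery of the ground-truth informative mask
#' (recall: selected informative variables / all informative variables) is
#' also reported.
#'
#' Selector workloads are scaled for a desk-scale study (CARS 30 repeats,
#' GSA 6 repeats with a population of 24 and early stopping); the selection
#' algorithms themselves are unchanged.
#'
#' @param n_seeds number of independent simulated datasets (default 10).
#' @param n_samples,n_points dataset size per seed (defaults 120 x 400).
#' @param analyte analyte to model (default `"cellulose"`).
#' @param selectors which variants to run besides `"full"`.
#' @param seed master seed.
#' @return A list with `rmsep` (matrix: variants x seeds), `recall`
#'   (per-seed CARS-GSA mask recall, `NA` if not run), `n_selected`
#'   (matrix of subset sizes), and `wins` (per-selector count of seeds
#'   beating the full spectrum).
#' @export
selector_benchmark <- function(n_seeds = 10L, n_samples = 120L,
                               n_points = 400L, analyte = "cellulose",
                               selectors = c("bipls", "cars", "bipls-cars",
                                             "bipls-gsa", "cars-gsa"),
                               seed = 1L) {
  selectors <- match.arg(selectors, several.ok = TRUE)
  variants <- c("full", selectors)
  rmsep <- matrix(NA_real_, length(variants), n_seeds,
                  dimnames = list(variants, NULL))
  nsel <- rmsep
  recall <- rep(NA_real_, n_seeds)
  cv <- cv_config("kfold", seed = 11L)
  cars_cfg <- cars_config(n_iterations = 100L, n_repeats = 30L, cv = cv)
  gsa_cfg <- gsa_config(pop_size = 24L, generations = 200L,
                        n_repeats = 6L, patience = 20L, cv = cv)

  for (si in seq_len(n_seeds)) {
    s <- derive_seed(seed, si)
    sim <- generate_spectra(default_stover_spec(n_samples = n_samples,
                                                n_points = n_points),
                            seed = s)
    ds <- sim$dataset
    pf <- preprocess_fit(ds$X, preprocess_spec("sg"), ds$axis)
    Xp <- preprocess_apply(pf, ds$X)
    y <- ds$y[[analyte]]
    sp <- spxy_split(Xp, y, round(2 / 3 * n_samples))
    Xc <- Xp[sp$cal_idx, , drop = FALSE]
    yc <- y[sp$cal_idx]
    Xv <- Xp[sp$val_idx, , drop = FALSE]
    yv <- y[sp$val_idx]
    cal <- spectra_dataset(ds$axis, Xc, lapply(ds$y, `[`, sp$cal_idx))

    eval_subset <- function(idx) {
      lv <- select_lv(Xc[, idx, drop = FALSE], yc,
                      cv_config("mccv", n_runs = 50L, seed = 99L))$lv
      m <- fit_pls(Xc[, idx, drop = FALSE], yc, lv)
      rmse(yv, predict(m, Xv[, idx, drop = FALSE]))
    }
    subsets <- list(full = seq_len(n_points))
    for (sel in selectors) {
      subsets[[sel]] <- switch(sel,
        "bipls" = bipls(cal, analyte, 20L, cv = cv)$subset,
        "cars" = cars_repeat(cal, analyte, cars_cfg, seed = s)$subset,
        "bipls-cars" = chain_select(cal, analyte, "bipls", "cars", 20L,
                                    cars_cfg, gsa_cfg, cv, seed = s)$subset,
        "bipls-gsa" = chain_select(cal, analyte, "bipls", "gsa", 20L,
                                   cars_cfg, gsa_cfg, cv, seed = s)$subset,
        "cars-gsa" = chain_select(cal, analyte, "cars", "gsa", 20L,
                                  cars_cfg, gsa_cfg, cv, seed = s)$subset)
    }
    for (v in variants) {
      rmsep[v, si] <- eval_subset(subsets[[v]])
      nsel[v, si] <- length(subsets[[v]])
    }
    if ("cars-gsa" %in% selectors) {
      mask <- which(sim$truth$informative_mask[[analyte]])
      recall[si] <- sum(subsets[["cars-gsa"]] %in% mask) / length(mask)
    }
  }
  wins <- rowSums(rmsep[selectors, , drop = FALSE] <
                    rep(rmsep["full", ], each = length(selectors)))
  list(rmsep = rmsep, recall = recall, n_selected = nsel, wins = wins)
}
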
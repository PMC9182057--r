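#' CARS configuration
#'
#' Parameters of competitive adaptive reweighted sampling. Each run performs
#' `n_iterations` rounds; in round `i` a Monte-Carlo calibration draw of
#' `mc_ratio` of the samples is fitted by PLS, variables are force-reduced to
#' the top `r_i * p` by absolute regression coefficient under the
#' exponentially decreasing function (EDF) `r_i = a * exp(-k * i)`, and the
#' survivors are then resampled by adaptive reweighted sampling (ARS),
#' weighted-with-replacement by coefficient magnitude. The EDF constants are
#' fixed by two boundary conditions: all `p` variables are retained at
#' `i = 1` and exactly 2 at `i = n_iterations`, giving
#' `k = log(p / 2) / (N - 1)` and `a = exp(k)`.
#'
#' @param n_iterations EDF iterations per run, N (default 100).
#' @param mc_ratio Monte-Carlo calibration fraction per iteration
#'   (default 0.8).
#' @param n_repeats independent CARS runs aggregated by [cars_repeat()]
#'   (default 200).
#' @param cv a [cv_config()] for subset RMSECV evaluation (deterministic
#'   `kfold` by default).
#' @param lv_cap latent-variable cap for the inner PLS fits (default 10).
#' @return An object of class `cars_config`.
#' @export
cars_config <- function(n_iterations = 100L, mc_ratio = 0.8,
                        n_repeats = 200L, cv = cv_config(scheme = "kfold"),
                        lv_cap = 10L) {
  if (n_iterations < 2) stop("n_iterations must be >= 2")
  if (mc_ratio <= 0 || mc_ratio >= 1) stop("mc_ratio must be in (0, 1)")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 mc_ratio = mc_ratio, n_repeats = as.integer(n_repeats),
                 cv = cv, lv_cap = as.integer(lv_cap)),
            class = "cars_config")
}

#' EDF retention constants
#'
#' Closed-form constants of the exponentially decreasing retention schedule,
#' fixed by keeping all `p` variables at iteration 1 and exactly 2 at
#' iteration `N`: `k = log(p / 2) / (N - 1)`, `a = exp(k)`.
#'
#' @param p number of candidate variables.
#' @param N number of EDF iterations.
#' @return A list with `a` and `k`.
#' @export
cars_edf_constants <- function(p, N) {
  if (p < 2 || N < 2) stop("need p >= 2 and N >= 2")
  k <- log(p / 2) / (N - 1)
  list(a = exp(k), k = k)
}

#' One CARS run
#'
#' A single competitive-adaptive-reweighted-sampling pass over the candidate
#' variables (see [cars_config()] for the algorithm). Every iteration's
#' surviving subset is scored by cross-validated RMSE on the full calibration
#' data; the subset with the global minimum RMSECV over all iterations is
#' returned.
#'
#' @param ds a [spectra_dataset()].
#' @param analyte analyte name.
#' @param cfg a [cars_config()].
#' @param seed RNG seed for the Monte-Carlo draws and ARS resampling.
#' @param candidates candidate column indices (default: the full spectrum);
#'   used by chains to restrict CARS to a first-stage subset.
#' @return A [selection_result()]; `trace` holds the per-iteration RMSECV
#'   and subset size.
#' @export
cars_once <- function(ds, analyte, cfg = cars_config(), seed = 1L,
                      candidates = seq_len(ncol(ds$X))) {
  stopifnot(inherits(ds, "spectra_dataset"), inherits(cfg, "cars_config"))
  y <- .get_analyte(ds, analyte)
  candidates <- sort(unique(as.integer(candidates)))
  p0 <- length(candidates)
  if (p0 < 2) stop("CARS needs at least 2 candidate variables")
  n <- nrow(ds$X)
  N <- cfg$n_iterations
  ed <- cars_edf_constants(p0, N)
  fcv <- .fitness_cv(cfg$cv, cfg$lv_cap)
  ncal <- max(2L, floor(cfg$mc_ratio * n))

  with_seed(seed, {
    vars <- candidates
    rec_subsets <- vector("list", N)
    rec_rmsecv <- rep(NA_real_, N)
    rec_lv <- rep(NA_integer_, N)
    rec_size <- rep(NA_integer_, N)
    for (i in seq_len(N)) {
      cal <- sample.int(n, ncal)
      A <- max(1L, min(cfg$lv_cap, length(vars), ncal - 1L))
      m <- fit_pls(ds$X[cal, vars, drop = FALSE], y[cal], A)
      w <- abs(m$b)
      if (all(w == 0)) w <- rep(1, length(w))
      # forced reduction by EDF: top r_i * p0 variables by |b|
      keep_n <- max(2L, min(length(vars),
                            round(ed$a * exp(-ed$k * i) * p0)))
      kept <- vars[order(w, decreasing = TRUE)[seq_len(keep_n)]]
      w_kept <- w[match(kept, vars)]
      # ARS: weighted sampling with replacement, then deduplicate
      drawn <- sample(kept, size = keep_n, replace = TRUE,
                      prob = w_kept / sum(w_kept))
      vars <- sort(unique(drawn))
      if (length(vars) < 2) { N <- i - 1L; break }
      f <- .subset_fitness(ds$X, y, vars, fcv)
      rec_subsets[[i]] <- vars
      rec_rmsecv[i] <- f$rmsecv
      rec_lv[i] <- f$lv
      rec_size[i] <- length(vars)
    }
  })
  ok <- which(!is.na(rec_rmsecv))
  if (length(ok) == 0) stop("CARS collapsed before scoring any subset")
  best <- ok[which.min(rec_rmsecv[ok])]
  selection_result(rec_subsets[[best]], "cars", rmsecv = rec_rmsecv[best],
                   cv = fcv, lv = rec_lv[best],
                   trace = data.frame(iteration = ok,
                                      n_vars = rec_size[ok],
                                      rmsecv = rec_rmsecv[ok]),
                   seed = seed,
                   details = list(edf = ed, best_iteration = best,
                                  candidates = candidates))
}

#' Repeated CARS with selection-frequency aggregation
#'
#' The Monte-Carlo draws and ARS make a single CARS run stochastic, so the
#' algorithm is repeated `cfg$n_repeats` times with independently derived
#' seeds. Per-candidate selection frequencies are counted over the winning
#' subsets of the runs, and the final subset is the single run's winner with
#' the global minimum RMSECV.
#'
#' @param ds a [spectra_dataset()].
#' @param analyte analyte name.
#' @param cfg a [cars_config()].
#' @param seed master seed; run seeds are derived from it.
#' @param candidates candidate column indices (default: full spectrum).
#' @return A [selection_result()]; `frequency` is a vector over `candidates`
#'   (named by column index) counting how many run winners contained each
#'   candidate; `trace` holds the sorted per-run RMSECVs.
#' @export
cars_repeat <- function(ds, analyte, cfg = cars_config(), seed = 1L,
                        candidates = seq_len(ncol(ds$X))) {
  stopifnot(inherits(cfg, "cars_config"))
  candidates <- sort(unique(as.integer(candidates)))
  R <- cfg$n_repeats
  runs <- lapply(seq_len(R), function(r)
    cars_once(ds, analyte, cfg, seed = derive_seed(seed, r),
              candidates = candidates))
  rmsecvs <- vapply(runs, `[[`, numeric(1), "rmsecv")
  freq <- stats::setNames(numeric(length(candidates)),
                          as.character(candidates))
  for (r in runs) {
    hit <- as.character(r$subset)
    freq[hit] <- freq[hit] + 1
  }
  best <- which.min(rmsecvs)
  selection_result(runs[[best]]$subset, "cars",
                   rmsecv = rmsecvs[best], cv = runs[[best]]$cv,
                   lv = runs[[best]]$lv, frequency = freq,
                   trace = sort(rmsecvs), seed = seed,
                   details = list(n_repeats = R, best_run = best,
                                  run_sizes = vapply(runs, function(r)
                                    length(r$subset), integer(1)),
                                  candidates = candidates))
}
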
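#' GSA configuration
#'
#' Parameters of the genetic simulated annealing selector: a binary-encoded
#' genetic algorithm (tournament selection, uniform crossover, bit-flip
#' mutation) whose replacement step follows the Metropolis criterion under a
#' geometric cooling schedule — a child worse than its parent by `delta` is
#' still accepted with probability `exp(-delta / T)`, and `T` is multiplied
#' by `alpha` each generation.
#'
#' Defaults follow the usual tuning for NIR wavelength reselection: initial
#' temperature 200, cooling coefficient 0.90, at most 200 generations,
#' population 50, crossover 0.8, per-bit mutation 0.02, tournament size 2.
#' `generations` is a maximum: a run stops early once the best fitness has
#' not improved for `patience` generations.
#'
#' @param pop_size population size (default 50).
#' @param t0 initial temperature (default 200).
#' @param alpha cooling coefficient in (0, 1) (default 0.90).
#' @param generations maximum number of generations (default 200).
#' @param crossover crossover probability (default 0.8).
#' @param mutation per-bit mutation probability (default 0.02).
#' @param n_repeats independent GSA runs aggregated by [gsa_select()]
#'   (default 30).
#' @param patience generations without improvement before early stop
#'   (default 40).
#' @param threshold_mode how the final subset is cut from the per-candidate
#'   selection frequencies: `"scan"` (default) evaluates the RMSECV of the
#'   subset induced by every frequency threshold and keeps the best;
#'   `"best_run"` simply returns the winner of the best single run.
#' @param cv a [cv_config()] for fitness evaluation.
#' @param lv_cap latent-variable cap for fitness models (default 10).
#' @return An object of class `gsa_config`.
#' @export
gsa_config <- function(pop_size = 50L, t0 = 200, alpha = 0.90,
                       generations = 200L, crossover = 0.8,
                       mutation = 0.02, n_repeats = 30L, patience = 40L,
                       threshold_mode = c("scan", "best_run"),
                       cv = cv_config(scheme = "kfold"), lv_cap = 10L) {
  threshold_mode <- match.arg(threshold_mode)
  if (t0 <= 0) stop("t0 must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (generations < 1) stop("generations must be >= 1")
  if (pop_size < 2) stop("pop_size must be >= 2")
  structure(list(pop_size = as.integer(pop_size), t0 = t0, alpha = alpha,
                 generations = as.integer(generations),
                 crossover = crossover, mutation = mutation,
                 n_repeats = as.integer(n_repeats),
                 patience = as.integer(patience),
                 threshold_mode = threshold_mode, cv = cv,
                 lv_cap = as.integer(lv_cap)),
            class = "gsa_config")
}

#' Metropolis acceptance decisions
#'
#' Accepts a deterioration `delta >= 0` with probability
#' `exp(-delta / temperature)`; improvements (`delta <= 0`) are always
#' accepted. Draws `n` independent decisions using the current RNG stream.
#'
#' @param delta fitness deterioration (child minus parent; minimization).
#' @param temperature current annealing temperature, `> 0`.
#' @param n number of decisions to draw.
#' @return Logical vector of length `n`.
#' @export
metropolis_accept <- function(delta, temperature, n = 1L) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (delta <= 0) return(rep(TRUE, n))
  runif(n) < exp(-delta / temperature)
}

# One GSA run over chromosomes of length m. Fitness is cached across the run
# (chromosomes recur heavily as the population converges).
.gsa_run <- function(X, y, candidates, cfg, fcv, seed) {
  m <- length(candidates)
  cache <- new.env(parent = emptyenv())
  fitness <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- .subset_fitness(X, y, candidates[bits], fcv)$rmsecv
    cache[[key]] <- val
    val
  }
  repair <- function(bits) {
    if (!any(bits)) bits[sample.int(m, 1)] <- TRUE
    bits
  }
  with_seed(seed, {
    pop <- lapply(seq_len(cfg$pop_size), function(i)
      repair(runif(m) < 0.5))
    fit <- vapply(pop, fitness, numeric(1))
    best_i <- which.min(fit)
    best <- list(bits = pop[[best_i]], fitness = fit[best_i])
    temp <- cfg$t0
    stall <- 0L
    for (g in seq_len(cfg$generations)) {
      tournament <- function() {
        ij <- sample.int(cfg$pop_size, 2)
        ij[which.min(fit[ij])]
      }
      new_pop <- pop
      new_fit <- fit
      for (s in seq_len(cfg$pop_size)) {
        i1 <- tournament(); i2 <- tournament()
        child <- if (runif(1) < cfg$crossover) {
          mask <- runif(m) < 0.5
          ifelse(mask, pop[[i1]], pop[[i2]])
        } else pop[[i1]]
        flip <- runif(m) < cfg$mutation
        child <- repair(xor(child, flip))
        fc <- fitness(child)
        delta <- fc - fit[i1]
        if (metropolis_accept(delta, temp)) {
          new_pop[[s]] <- child
          new_fit[s] <- fc
        } else {
          new_pop[[s]] <- pop[[i1]]
          new_fit[s] <- fit[i1]
        }
      }
      pop <- new_pop
      fit <- new_fit
      gen_best <- which.min(fit)
      if (fit[gen_best] < best$fitness - 1e-15) {
        best <- list(bits = pop[[gen_best]], fitness = fit[gen_best])
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= cfg$patience) break
      temp <- temp * cfg$alpha
    }
  })
  best
}

#' Genetic simulated annealing wavelength reselection
#'
#' Reselects characteristic wavelengths from a candidate subset (typically
#' the output of BIPLS or CARS, which keeps the chromosome length — and thus
#' the solution space — manageable). Chromosomes are binary inclusion masks
#' over `candidates`; fitness is the cross-validated RMSE of a PLS model on
#' the active variables. The GA evolves with tournament selection, uniform
#' crossover and bit-flip mutation, and children replace their parent
#' according to the Metropolis criterion under geometric cooling (see
#' [gsa_config()]).
#'
#' The run is repeated `cfg$n_repeats` times; per-candidate selection
#' frequencies are counted over the run winners, and the final subset is cut
#' at the frequency threshold whose induced subset has the smallest RMSECV
#' (or the best run's winner, per `cfg$threshold_mode`).
#'
#' @param ds a [spectra_dataset()].
#' @param analyte analyte name.
#' @param candidates candidate column indices (length >= 2).
#' @param cfg a [gsa_config()].
#' @param seed master seed; run seeds are derived from it.
#' @return A [selection_result()]; `frequency` counts run winners per
#'   candidate, `trace` holds per-run best RMSECVs, and
#'   `details$threshold` the chosen frequency cut.
#' @export
gsa_select <- function(ds, analyte, candidates, cfg = gsa_config(),
                       seed = 1L) {
  stopifnot(inherits(ds, "spectra_dataset"), inherits(cfg, "gsa_config"))
  y <- .get_analyte(ds, analyte)
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) < 2) stop("GSA needs at least 2 candidates")
  if (max(candidates) > ncol(ds$X) || min(candidates) < 1)
    stop("candidate index out of range")
  fcv <- .fitness_cv(cfg$cv, cfg$lv_cap)
  runs <- lapply(seq_len(cfg$n_repeats), function(r)
    .gsa_run(ds$X, y, candidates, cfg, fcv, derive_seed(seed, 100L + r)))
  run_fit <- vapply(runs, `[[`, numeric(1), "fitness")
  freq <- colSums(do.call(rbind, lapply(runs, `[[`, "bits")))
  names(freq) <- as.character(candidates)
  best_run <- which.min(run_fit)

  if (cfg$threshold_mode == "best_run" || max(freq) == 0) {
    subset <- candidates[runs[[best_run]]$bits]
    f <- .subset_fitness(ds$X, y, subset, fcv)
    threshold <- NA_integer_
  } else {
    # scan frequency thresholds; subset = candidates selected >= t times
    thresholds <- seq_len(max(freq))
    scan <- lapply(thresholds, function(t) {
      sub <- candidates[freq >= t]
      if (length(sub) < 1) return(list(rmsecv = Inf, lv = NA_integer_))
      .subset_fitness(ds$X, y, sub, fcv)
    })
    sc_rmsecv <- vapply(scan, `[[`, numeric(1), "rmsecv")
    t_best <- thresholds[which.min(sc_rmsecv)]
    threshold <- t_best
    subset <- candidates[freq >= t_best]
    f <- scan[[which.min(sc_rmsecv)]]
  }
  selection_result(subset, "gsa", rmsecv = f$rmsecv, cv = fcv, lv = f$lv,
                   frequency = freq, trace = run_fit, seed = seed,
                   details = list(threshold = threshold,
                                  best_run = best_run,
                                  candidates = candidates))
}
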
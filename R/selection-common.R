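# Shared infrastructure for the wavelength selectors.

#' Selection result container
#'
#' Every selector returns one of these: the chosen wavelength subset (1-based
#' column indices into the dataset the selector ran on), the RMSECV it
#' achieved, per-candidate selection frequencies where the selector is
#' repeated, a per-iteration trace, and enough provenance (selector name,
#' cross-validation configuration, seed) to recompute the achieved RMSECV
#' exactly.
#'
#' @param subset integer vector of selected column indices.
#' @param source selector name (e.g. `"cars"`, `"bipls-gsa"`).
#' @param rmsecv achieved cross-validated RMSE of the subset.
#' @param cv the [cv_config()] under which `rmsecv` was computed.
#' @param lv latent-variable count at which `rmsecv` was reached.
#' @param frequency optional numeric vector of per-candidate selection counts.
#' @param trace optional per-iteration RMSECV record.
#' @param seed seed governing the selector's randomness (`NA` for
#'   deterministic selectors).
#' @param details free-form provenance list.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(subset, source, rmsecv, cv, lv = NA_integer_,
                             frequency = NULL, trace = NULL,
                             seed = NA_integer_, details = list()) {
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) < 1) stop("selection produced an empty subset")
  structure(list(subset = subset, source = source, rmsecv = rmsecv,
                 lv = lv, frequency = frequency, trace = trace,
                 cv = cv, seed = seed, details = details),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$source, "]: ", length(x$subset),
      " wavelength variables, RMSECV = ", format(x$rmsecv, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# Selector fitness: cross-validated RMSE of the PLS model on a column subset,
# minimized over the latent-variable count. Inner-loop models are capped at
# 10 LVs to keep selector loops cheap; final models re-select LVs properly.
.fitness_cv <- function(cv, lv_cap = 10L) {
  cv$lv_max <- min(cv$lv_max, lv_cap)
  cv
}

.subset_fitness <- function(X, y, idx, cv) {
  curve <- rmsecv_curve(X[, idx, drop = FALSE], y, cv)
  list(rmsecv = min(curve), lv = which.min(curve))
}

#' Export a selection result to JSON
#' @param res a [selection_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(res, path) {
  stopifnot(inherits(res, "selection_result"))
  obj <- list(source = res$source, subset = res$subset,
              n_selected = length(res$subset), rmsecv = res$rmsecv,
              lv = res$lv, seed = res$seed,
              cv = unclass(res$cv), frequency = res$frequency,
              trace = res$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Chain two wavelength selectors
#'
#' Runs the first-stage selector on the full spectrum and the second-stage
#' selector restricted to the first stage's subset, so the second stage can
#' only keep or discard variables the first stage retained. Supported pairs:
#' BIPLS->CARS, BIPLS->GSA, CARS->GSA.
#'
#' @param ds a [spectra_dataset()].
#' @param analyte analyte name.
#' @param first `"bipls"` or `"cars"`.
#' @param second `"cars"` or `"gsa"`.
#' @param bipls_n_intervals interval count (or vector to scan) for a BIPLS
#'   first stage.
#' @param cars_cfg a [cars_config()] for a CARS stage.
#' @param gsa_cfg a [gsa_config()] for a GSA second stage.
#' @param cv a [cv_config()] for BIPLS and for the final RMSECV.
#' @param seed master seed; stage seeds are derived from it.
#' @return A [selection_result()] whose `subset` indexes the original
#'   spectrum; `details$first_stage` holds the first-stage result.
#' @export
chain_select <- function(ds, analyte, first = c("bipls", "cars"),
                         second = c("cars", "gsa"),
                         bipls_n_intervals = 20L,
                         cars_cfg = cars_config(),
                         gsa_cfg = gsa_config(),
                         cv = cv_config(scheme = "kfold"), seed = 1L) {
  first <- match.arg(first)
  second <- match.arg(second)
  if (first == "cars" && second == "cars")
    stop("unsupported chain: cars -> cars")
  if (second == "cars" && first != "bipls")
    stop("supported chains: bipls->cars, bipls->gsa, cars->gsa")
  s1 <- if (first == "bipls") {
    if (length(bipls_n_intervals) > 1)
      bipls_scan(ds, analyte, bipls_n_intervals, cv = cv)$best_result
    else bipls(ds, analyte, bipls_n_intervals, cv = cv)
  } else {
    cars_repeat(ds, analyte, cars_cfg, seed = derive_seed(seed, 1L))
  }
  if (length(s1$subset) < 2)
    stop("first stage returned fewer than 2 variables")
  s2 <- if (second == "cars") {
    cars_repeat(ds, analyte, cars_cfg, candidates = s1$subset,
                seed = derive_seed(seed, 2L))
  } else {
    gsa_select(ds, analyte, candidates = s1$subset, cfg = gsa_cfg,
               seed = derive_seed(seed, 2L))
  }
  selection_result(s2$subset, paste(first, second, sep = "-"),
                   rmsecv = s2$rmsecv, cv = s2$cv, lv = s2$lv,
                   frequency = s2$frequency, trace = s2$trace, seed = seed,
                   details = list(first_stage = s1, second_stage = s2))
}
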
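#' Define a synthetic NIR dataset specification
#'
#' Describes a corn-stover-like NIR simulation: a wavenumber axis, analyte
#' components with concentration ranges and Gaussian absorption bands,
#' low-order polynomial baseline drift, per-sample multiplicative scatter,
#' additive white noise, and optional reference-value outlier injection.
#' Pass the spec to [generate_spectra()].
#'
#' Each component's pure spectrum is a sum of Gaussian bands
#' `height * exp(-(axis - center)^2 / (2 * width^2))` (width = Gaussian
#' sigma, in cm^-1), with `height` in absorbance units per percent analyte,
#' so a mixture spectrum is `sum_k concentration_k * pure_k`.
#'
#' @param n_samples number of samples.
#' @param axis_start,axis_stop,n_points wavenumber axis (cm^-1), ascending.
#' @param components named list; each element is
#'   `list(range = c(lo, hi), bands = data.frame(center, width, height))`.
#' @param baseline_sd standard deviation of the random quadratic baseline
#'   coefficients (absorbance units).
#' @param scatter_sd standard deviation of the per-sample multiplicative
#'   scatter field (the factor is `1 + eps(lambda)`).
#' @param scatter_harmonics number of cosine harmonics in the per-sample
#'   scatter field. `0` gives the classical single global factor
#'   `1 + eps`; larger values emulate wavelength-dependent scatter from
#'   particle-size and packing variation, a smooth multiplicative nuisance
#'   that a single MSC slope cannot fully remove (the dominant artifact in
#'   diffuse reflectance of ground solids). Harmonic amplitudes decay as
#'   `scatter_sd / (1 + j)`.
#' @param noise_sd additive white-noise standard deviation (absorbance
#'   units).
#' @param n_outliers number of samples whose reference values are corrupted.
#' @param outlier_shift magnitude of the corruption, in multiples of each
#'   analyte's reference-value standard deviation (random sign).
#' @param interferents named list with the same structure as `components`:
#'   constituents that vary from sample to sample and absorb in the recorded
#'   range but are not modeled analytes (lignin, moisture, protein in real
#'   stover). Their bands corrupt off-band spectral regions with variance
#'   uncorrelated to the analytes — the reason wavelength selection pays off
#'   on real spectra. Empty by default.
#' @param background optional stable matrix absorbance shared by all
#'   samples: `list(offset = , bands = data.frame(center, width, height))`
#'   with heights in absolute absorbance units. Emulates the constituents
#'   not modeled as analytes (lignin, moisture), whose broad absorbance
#'   dominates total intensity in real biomass spectra and makes
#'   multiplicative scatter separable from analyte signal. `NULL` (default)
#'   means no background.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 120L, axis_start = 3940,
                           axis_stop = 11542, n_points = 1845L,
                           components = list(), baseline_sd = 0.02,
                           scatter_sd = 0.05, noise_sd = 0.0025,
                           n_outliers = 0L, outlier_shift = 10,
                           scatter_harmonics = 4L,
                           interferents = list(), background = NULL) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (axis_stop <= axis_start) stop("axis_stop must exceed axis_start")
  if (noise_sd < 0 || scatter_sd < 0 || baseline_sd < 0)
    stop("noise/scatter/baseline standard deviations must be >= 0")
  if (length(components) == 0 || is.null(names(components)))
    stop("components must be a named list")
  if (length(interferents) > 0 && is.null(names(interferents)))
    stop("interferents must be a named list")
  for (nm in names(c(components, interferents))) {
    comp <- c(components, interferents)[[nm]]
    if (length(comp$range) != 2 || comp$range[1] >= comp$range[2])
      stop("component '", nm, "': range must be c(lo, hi) with lo < hi")
    b <- comp$bands
    if (!all(c("center", "width", "height") %in% names(b)))
      stop("component '", nm, "': bands need center, width, height")
    if (any(b$center < axis_start | b$center > axis_stop))
      stop("component '", nm, "': band center outside the axis")
    if (any(b$width <= 0) || any(b$height <= 0))
      stop("component '", nm, "': widths and heights must be positive")
  }
  if (!is.null(background)) {
    b <- background$bands
    if (!is.null(b) &&
        (!all(c("center", "width", "height") %in% names(b)) ||
         any(b$center < axis_start | b$center > axis_stop)))
      stop("background bands need center/width/height on the axis")
  }
  structure(list(n_samples = as.integer(n_samples),
                 axis_start = axis_start, axis_stop = axis_stop,
                 n_points = as.integer(n_points), components = components,
                 baseline_sd = baseline_sd, scatter_sd = scatter_sd,
                 noise_sd = noise_sd, n_outliers = as.integer(n_outliers),
                 outlier_shift = outlier_shift,
                 scatter_harmonics = as.integer(scatter_harmonics),
                 interferents = interferents, background = background),
            class = "synthetic_spec")
}

#' Default corn-stover-like simulation
#'
#' Two analytes with the concentration ranges observed in corn stover
#' calibration sets (cellulose 36.067-51.527 %, hemicellulose
#' 9.484-38.541 %) and partially overlapping Gaussian bands placed at the
#' prominent stover NIR absorption peaks (6817, 5182, 4749 and 4292 cm^-1):
#' cellulose loads on 6817/5182/4749, hemicellulose on 5182/4749/4292, so
#' each analyte also has a private band and both remain identifiable. The
#' default axis matches a 3940-11542 cm^-1 instrument range sampled at 1845
#' points.
#'
#' The default also includes two interfering constituents that vary between
#' samples but are not analytes — a lignin-like component (bands near 8600,
#' 5980 and 4680 cm^-1) and a moisture-like component (strong O-H bands near
#' 6900 and 5150 cm^-1) — plus a broad stable matrix background. The
#' interferents give the off-band spectral regions genuine, analyte-
#' uncorrelated variance, which is what makes full-spectrum models
#' suboptimal and wavelength selection worthwhile on real biomass spectra.
#'
#' @param n_samples number of samples (default 120).
#' @param n_points axis length (default 1845).
#' @param ... further arguments passed to [synthetic_spec()] (noise,
#'   scatter, outlier injection, ...).
#' @return A [synthetic_spec()].
#' @export
default_stover_spec <- function(n_samples = 120L, n_points = 1845L, ...) {
  synthetic_spec(
    n_samples = n_samples, n_points = n_points,
    components = list(
      cellulose = list(
        range = c(36.067, 51.527),
        bands = data.frame(center = c(6817, 5182, 4749),
                           width = c(160, 120, 100),
                           height = c(0.010, 0.013, 0.009))),
      hemicellulose = list(
        range = c(9.484, 38.541),
        bands = data.frame(center = c(5182, 4749, 4292),
                           width = c(120, 100, 90),
                           height = c(0.008, 0.011, 0.010)))),
    interferents = list(
      lignin = list(
        range = c(12, 28),
        bands = data.frame(center = c(8600, 5980, 4680),
                           width = c(250, 140, 110),
                           height = c(0.008, 0.012, 0.010))),
      moisture = list(
        range = c(3, 9),
        bands = data.frame(center = c(6900, 5150),
                           width = c(180, 150),
                           height = c(0.030, 0.035)))),
    background = list(
      offset = 0.25,
      bands = data.frame(center = c(7000, 5200, 4400),
                         width = c(1200, 900, 500),
                         height = c(0.20, 0.25, 0.20))),
    ...)
}

#' Generate a synthetic NIR dataset
#'
#' Draws per-sample concentrations uniformly within each component's range,
#' builds mixture spectra as concentration-weighted sums of the pure
#' component spectra plus a smooth random quadratic baseline, applies a
#' per-sample multiplicative scatter factor `1 + eps`, adds white noise, and
#' optionally corrupts the reference values of a few samples (y-outliers).
#' Bit-identical for a given seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed.
#' @return A list with `dataset` (a [spectra_dataset()]) and `truth`:
#'   `concentrations` (n x analytes matrix of the uncorrupted values),
#'   `pure_spectra`, `informative_mask` (per analyte, logical over the axis:
#'   within 2 widths of one of its band centers), `outlier_idx` /
#'   `outlier_ids`, and the seed.
#' @examples
#' sim <- generate_spectra(default_stover_spec(n_samples = 20,
#'                                             n_points = 200), seed = 7)
#' sim$dataset
#' @export
generate_spectra <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  axis <- seq(spec$axis_start, spec$axis_stop, length.out = spec$n_points)
  comps <- names(spec$components)
  pure <- vapply(comps, function(nm) {
    b <- spec$components[[nm]]$bands
    rowSums(vapply(seq_len(nrow(b)), function(i)
      b$height[i] * exp(-(axis - b$center[i])^2 / (2 * b$width[i]^2)),
      numeric(length(axis))))
  }, numeric(length(axis)))  # p x n_comp
  mask <- lapply(comps, function(nm) {
    b <- spec$components[[nm]]$bands
    Reduce(`|`, lapply(seq_len(nrow(b)), function(i)
      abs(axis - b$center[i]) <= 2 * b$width[i]))
  })
  names(mask) <- comps
  bg <- numeric(length(axis))
  if (!is.null(spec$background)) {
    if (!is.null(spec$background$offset)) bg <- bg + spec$background$offset
    b <- spec$background$bands
    if (!is.null(b))
      bg <- bg + rowSums(vapply(seq_len(nrow(b)), function(i)
        b$height[i] * exp(-(axis - b$center[i])^2 / (2 * b$width[i]^2)),
        numeric(length(axis))))
  }
  intf <- names(spec$interferents)
  pure_intf <- vapply(intf, function(nm) {
    b <- spec$interferents[[nm]]$bands
    rowSums(vapply(seq_len(nrow(b)), function(i)
      b$height[i] * exp(-(axis - b$center[i])^2 / (2 * b$width[i]^2)),
      numeric(length(axis))))
  }, numeric(length(axis)))
  n <- spec$n_samples
  with_seed(seed, {
    conc <- vapply(comps, function(nm)
      runif(n, spec$components[[nm]]$range[1],
            spec$components[[nm]]$range[2]), numeric(n))
    conc <- matrix(conc, nrow = n, dimnames = list(NULL, comps))
    clean <- conc %*% t(pure) + rep(bg, each = n)
    conc_intf <- NULL
    if (length(intf)) {
      conc_intf <- vapply(intf, function(nm)
        runif(n, spec$interferents[[nm]]$range[1],
              spec$interferents[[nm]]$range[2]), numeric(n))
      conc_intf <- matrix(conc_intf, nrow = n,
                          dimnames = list(NULL, intf))
      clean <- clean + conc_intf %*% t(matrix(pure_intf,
                                              ncol = length(intf)))
    }
    u <- (axis - spec$axis_start) / (spec$axis_stop - spec$axis_start)
    bl_coef <- matrix(rnorm(3 * n, 0, spec$baseline_sd), n, 3)
    baseline <- bl_coef %*% rbind(1, u, u^2)
    # smooth multiplicative scatter field: 1 + sum_j a_j cos(j pi u),
    # amplitudes decaying with harmonic order (j = 0 is the global factor)
    H <- spec$scatter_harmonics
    amp <- spec$scatter_sd / (1 + 0:H)
    coefs <- matrix(rnorm(n * (H + 1)), n) * rep(amp, each = n)
    basis <- t(vapply(0:H, function(j) cos(j * pi * u),
                      numeric(length(u))))
    scatter <- 1 + coefs %*% basis
    X <- scatter * (clean + baseline) +
      matrix(rnorm(n * length(axis), 0, spec$noise_sd), n)
    y <- as.list(as.data.frame(conc))
    outlier_idx <- integer(0)
    if (spec$n_outliers > 0) {
      outlier_idx <- sort(sample.int(n, min(spec$n_outliers, n)))
      for (nm in comps) {
        shift <- spec$outlier_shift * sd(conc[, nm]) *
          sample(c(-1, 1), length(outlier_idx), replace = TRUE)
        y[[nm]][outlier_idx] <- y[[nm]][outlier_idx] + shift
      }
    }
  })
  ds <- spectra_dataset(axis, X, y)
  list(dataset = ds,
       truth = list(concentrations = conc,
                    interferent_concentrations = conc_intf,
                    pure_spectra = pure,
                    informative_mask = mask, outlier_idx = outlier_idx,
                    outlier_ids = ds$ids[outlier_idx], seed = seed))
}
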
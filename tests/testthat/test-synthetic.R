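test_that("a single noise-free band yields spectra proportional to it", {
  spec <- synthetic_spec(
    n_samples = 5, axis_start = 4000, axis_stop = 6000, n_points = 50,
    components = list(a = list(range = c(10, 30),
                               bands = data.frame(center = 5000,
                                                  width = 150,
                                                  height = 0.02))),
    baseline_sd = 0, scatter_sd = 0, noise_sd = 0)
  sim <- generate_spectra(spec, seed = 2)
  axis <- sim$dataset$axis
  band <- 0.02 * exp(-(axis - 5000)^2 / (2 * 150^2))
  for (i in 1:5)
    expect_equal(sim$dataset$X[i, ], sim$truth$concentrations[i, "a"] * band,
                 tolerance = 1e-12)
})

test_that("default stover spec has the documented axis, ranges and masks", {
  spec <- default_stover_spec()
  expect_equal(spec$n_points, 1845L)
  expect_equal(spec$components$cellulose$range, c(36.067, 51.527))
  expect_equal(spec$components$hemicellulose$range, c(9.484, 38.541))
  sim <- generate_spectra(default_stover_spec(n_samples = 200,
                                              n_points = 300), seed = 3)
  expect_true(all(sim$dataset$y$cellulose >= 36.067 &
                    sim$dataset$y$cellulose <= 51.527))
  expect_true(all(sim$dataset$y$hemicellulose >= 9.484 &
                    sim$dataset$y$hemicellulose <= 38.541))
  # informative mask: within 2 widths of one of the analyte's band centers
  m <- sim$truth$informative_mask$cellulose
  axis <- sim$dataset$axis
  b <- spec$components$cellulose$bands
  oracle <- rep(FALSE, length(axis))
  for (i in seq_len(nrow(b)))
    oracle <- oracle | abs(axis - b$center[i]) <= 2 * b$width[i]
  expect_equal(m, oracle)
})

test_that("generation is bit-identical for a fixed seed", {
  s1 <- make_small_sim(n = 10, p = 40, seed = 9)
  s2 <- make_small_sim(n = 10, p = 40, seed = 9)
  expect_identical(s1, s2)
  s3 <- make_small_sim(n = 10, p = 40, seed = 10)
  expect_false(identical(s1$dataset$X, s3$dataset$X))
})

test_that("invalid specifications are rejected", {
  bands <- data.frame(center = 5000, width = 100, height = 0.01)
  expect_error(synthetic_spec(components = list(a = list(
    range = c(10, 30), bands = data.frame(center = 99, width = 10,
                                          height = 1)))), "outside the axis")
  expect_error(synthetic_spec(components = list(a = list(
    range = c(30, 10), bands = bands))), "range")
  expect_error(synthetic_spec(components = list(a = list(
    range = c(10, 30), bands = bands)), noise_sd = -1), ">= 0")
  expect_error(synthetic_spec(components = list()), "named list")
})

test_that("without scatter and noise, concentrations are recovered exactly", {
  sim <- generate_spectra(default_stover_spec(
    n_samples = 40, n_points = 120, scatter_sd = 0, noise_sd = 0,
    baseline_sd = 0), seed = 12)
  ds <- sim$dataset
  # rank = 2 analytes + 2 interferents, so 4 components span the spectra
  for (an in c("cellulose", "hemicellulose")) {
    m <- fit_pls(ds$X, ds$y[[an]], 4)
    expect_gt(r2(ds$y[[an]], predict(m, ds$X)), 1 - 1e-9)
  }
  # SNV and MSC keep the relation essentially identifiable (their
  # sample-wise rescaling is a mildly nonlinear map of the concentrations,
  # so a linear model retains R^2 near, but not exactly, 1)
  for (Xp in list(snv(ds$X), msc(ds$X))) {
    m <- fit_pls(Xp, ds$y$cellulose, 4)
    expect_gt(r2(ds$y$cellulose, predict(m, Xp)), 0.99)
  }
})

test_that("injected y-outliers are recorded in the ground truth", {
  sim <- generate_spectra(default_stover_spec(
    n_samples = 30, n_points = 50, n_outliers = 2, outlier_shift = 6),
    seed = 21)
  expect_length(sim$truth$outlier_idx, 2)
  idx <- sim$truth$outlier_idx
  expect_false(any(sim$dataset$y$cellulose[idx] ==
                     sim$truth$concentrations[idx, "cellulose"]))
  clean <- setdiff(seq_len(30), idx)
  expect_equal(sim$dataset$y$cellulose[clean],
               unname(sim$truth$concentrations[clean, "cellulose"]))
})
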
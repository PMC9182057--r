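# Shared small dataset with a planted band structure
sel_sim <- make_small_sim(n = 50, p = 80, seed = 31)
sel_ds <- sel_sim$dataset
sel_cv <- cv_config("kfold", seed = 5, lv_max = 8)

test_that("bipls keeps the informative interval and drops pure noise", {
  set.seed(71)
  n <- 40
  good <- matrix(rnorm(n * 10), n)
  y <- drop(good %*% rnorm(10)) + rnorm(n, 0, 0.05)
  noise <- matrix(rnorm(n * 10, 0, 1), n)
  ds <- spectra_dataset(seq_len(20), cbind(good, noise), list(a = y))
  r <- bipls(ds, "a", 2, cv = sel_cv)
  expect_equal(r$subset, 1:10)
  expect_equal(nrow(r$trace), 2)  # start + one elimination
})

test_that("bipls trace, intervals and trivial n = 1 behave as specified", {
  r1 <- bipls(sel_ds, "cellulose", 1, cv = sel_cv)
  expect_equal(r1$subset, seq_len(80))
  expect_equal(nrow(r1$trace), 1)
  # interval widths: floor(p/n) with the remainder spread from the first
  iv <- nirsel:::.make_intervals(11, 3)
  expect_equal(lengths(iv), c(4L, 4L, 3L))
  expect_equal(unlist(iv), 1:11)
  r <- bipls(sel_ds, "cellulose", 5, cv = sel_cv)
  expect_equal(nrow(r$trace), 5)  # one row per elimination level
  expect_error(bipls(sel_ds, "cellulose", 100, cv = sel_cv), "exceeds")
})

test_that("bipls equals an independent re-implementation of the greedy rule", {
  y <- sel_ds$y$cellulose
  fcv <- nirsel:::.fitness_cv(sel_cv)
  fitness <- function(idx) min(rmsecv_curve(sel_ds$X[, idx, drop = FALSE],
                                            y, fcv))
  for (n_int in c(3, 4)) {
    intervals <- nirsel:::.make_intervals(ncol(sel_ds$X), n_int)
    oracle <- bipls_oracle(intervals, fitness)
    got <- bipls(sel_ds, "cellulose", n_int, cv = sel_cv)
    expect_equal(got$subset, sort(unlist(intervals[oracle$alive])))
    expect_equal(got$rmsecv, oracle$rmsecv, tolerance = 1e-12)
  }
})

test_that("bipls_scan picks the best interval count and refines the bracket", {
  one <- bipls_scan(sel_ds, "cellulose", 4, cv = sel_cv)
  expect_equal(one$best_n, 4)
  sc <- bipls_scan(sel_ds, "cellulose", c(4, 8, 16), refine = TRUE,
                   cv = sel_cv)
  expect_true(all(c("n", "n_selected_intervals", "rmsecv",
                    "n_wavelengths") %in% names(sc$table)))
  # refinement fills the integer bracket between the two best coarse counts
  coarse <- sc$table[sc$table$n %in% c(4, 8, 16), ]
  top2 <- sort(coarse$n[order(coarse$rmsecv)][1:2])
  expect_setequal(setdiff(seq(top2[1], top2[2]), c(4, 8, 16)),
                  setdiff(sc$table$n, c(4, 8, 16)))
  expect_equal(sc$best_n, sc$table$n[which.min(sc$table$rmsecv)])
  # achieved RMSECV is reproducible from the stored subset and cv
  best <- sc$best_result
  expect_equal(min(rmsecv_curve(sel_ds$X[, best$subset, drop = FALSE],
                                sel_ds$y$cellulose, best$cv)),
               best$rmsecv)
})

test_that("the EDF retention schedule honors its boundary conditions", {
  ed <- cars_edf_constants(100, 100)
  expect_equal(ed$k, log(50) / 99, tolerance = 1e-12)
  expect_equal(ed$a, exp(log(50) / 99), tolerance = 1e-12)
  for (pN in list(c(100, 100), c(1845, 100), c(60, 50), c(7, 9))) {
    p <- pN[1]; N <- pN[2]
    ed <- cars_edf_constants(p, N)
    counts <- round(ed$a * exp(-ed$k * seq_len(N)) * p)
    expect_equal(counts[1], p)       # iteration 1 retains everything
    expect_equal(counts[N], 2)       # final iteration keeps exactly 2
    expect_true(all(diff(counts) <= 0))  # forced reduction never grows
  }
})

test_that("cars recovers planted informative variables", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(800 + s)
    n <- 60; p <- 60
    info <- c(5, 17, 29, 41, 53)
    X <- matrix(rnorm(n * p), n)
    sig <- drop(X[, info] %*% rep(1, 5))
    y <- sig + rnorm(n, 0, sd(sig) / 20)  # SNR ~ 20
    ds <- spectra_dataset(seq_len(p), X, list(a = y))
    r <- cars_once(ds, "a", cars_config(n_iterations = 50), seed = s)
    if (sum(info %in% r$subset) >= 4) wins <- wins + 1L
  }
  expect_gte(wins, 8)
})

test_that("cars_repeat aggregates runs reproducibly", {
  cfg <- cars_config(n_iterations = 30, n_repeats = 4)
  r <- cars_repeat(sel_ds, "cellulose", cfg, seed = 3)
  # frequency accounting: total counts = sum of winning subset sizes
  expect_equal(sum(r$frequency), sum(r$details$run_sizes))
  expect_equal(r$trace, sort(r$trace))
  expect_length(r$trace, 4)
  expect_identical(r, cars_repeat(sel_ds, "cellulose", cfg, seed = 3))
  # a single repeat reduces to cars_once under the derived seed
  cfg1 <- cars_config(n_iterations = 30, n_repeats = 1)
  r1 <- cars_repeat(sel_ds, "cellulose", cfg1, seed = 3)
  once <- cars_once(sel_ds, "cellulose", cfg1,
                    seed = nirsel:::derive_seed(3, 1))
  expect_equal(r1$subset, once$subset)
  expect_equal(r1$rmsecv, once$rmsecv)
  # achieved RMSECV is recomputable from the stored provenance
  expect_equal(min(rmsecv_curve(sel_ds$X[, r$subset, drop = FALSE],
                                sel_ds$y$cellulose, r$cv)), r$rmsecv)
})

test_that("metropolis acceptance follows exp(-delta/T)", {
  expect_true(all(metropolis_accept(-3, 200, 10)))
  expect_true(all(metropolis_accept(0, 1, 5)))
  expect_equal(exp(-20 / 200), 0.904837, tolerance = 1e-6)
  expect_error(metropolis_accept(1, 0), "temperature")
})

test_that("gsa finds near-optimal subsets of a small candidate pool", {
  agree <- 0L
  for (s in 1:10) {
    set.seed(900 + s)
    n <- 30; m <- 10
    X <- matrix(rnorm(n * m), n)
    y <- drop(X[, c(2, 7)] %*% c(1, 1)) + rnorm(n, 0, 0.05)
    ds <- spectra_dataset(seq_len(m), X, list(a = y))
    cv <- cv_config("kfold", seed = 17, lv_max = 4)
    fcv <- nirsel:::.fitness_cv(cv)
    # exhaustive oracle over all nonempty subsets
    best_rmsecv <- Inf
    for (code in 1:(2^m - 1)) {
      idx <- which(bitwAnd(code, 2^(0:(m - 1))) > 0)
      v <- min(rmsecv_curve(X[, idx, drop = FALSE], y, fcv))
      if (v < best_rmsecv) best_rmsecv <- v
    }
    g <- gsa_select(ds, "a", candidates = seq_len(m),
                    cfg = gsa_config(pop_size = 20, generations = 30,
                                     n_repeats = 3, patience = 10,
                                     cv = cv),
                    seed = s)
    if (g$rmsecv <= best_rmsecv * 1.01) agree <- agree + 1L
  }
  expect_gte(agree, 8)
})

test_that("gsa respects candidate space and reports frequencies", {
  cand <- seq(5, 60, by = 5)
  g <- gsa_select(sel_ds, "cellulose", candidates = cand,
                  cfg = gsa_config(pop_size = 12, generations = 15,
                                   n_repeats = 3, patience = 5,
                                   cv = sel_cv),
                  seed = 2)
  expect_true(all(g$subset %in% cand))
  expect_named(g$frequency, as.character(cand))
  expect_true(all(g$frequency <= 3))
  expect_length(g$trace, 3)
  g2 <- gsa_select(sel_ds, "cellulose", candidates = cand,
                   cfg = gsa_config(pop_size = 12, generations = 15,
                                    n_repeats = 3, patience = 5,
                                    cv = sel_cv),
                   seed = 2)
  expect_identical(g$subset, g2$subset)
  expect_error(gsa_select(sel_ds, "cellulose", candidates = 3,
                          cfg = gsa_config()), "at least 2")
})

test_that("chained selectors stay inside the first stage's subset", {
  cfg_cars <- cars_config(n_iterations = 30, n_repeats = 3)
  cfg_gsa <- gsa_config(pop_size = 12, generations = 15, n_repeats = 3,
                        patience = 5, cv = sel_cv)
  bc <- chain_select(sel_ds, "cellulose", "bipls", "cars",
                     bipls_n_intervals = 8, cars_cfg = cfg_cars,
                     cv = sel_cv, seed = 4)
  expect_true(all(bc$subset %in% bc$details$first_stage$subset))
  expect_equal(bc$source, "bipls-cars")
  cg <- chain_select(sel_ds, "cellulose", "cars", "gsa",
                     cars_cfg = cfg_cars, gsa_cfg = cfg_gsa,
                     cv = sel_cv, seed = 4)
  expect_true(all(cg$subset %in% cg$details$first_stage$subset))
  expect_lte(length(cg$subset), length(cg$details$first_stage$subset))
  expect_error(chain_select(sel_ds, "cellulose", "cars", "cars"),
               "chain")
})
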
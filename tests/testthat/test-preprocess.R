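test_that("SNV centers and scales rows, rejects constant spectra", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  z <- matrix(c(-1, 0, 1, -2, 0, 2), 2, byrow = TRUE) / c(1, 2)
  expect_equal(snv(z), z)  # already zero-mean unit-sd rows
  expect_error(snv(matrix(c(5, 5, 5), 1)), "sample 1")
})

test_that("MSC removes affine scatter and matches the normal-equations oracle", {
  ref <- c(0.2, 0.5, 0.9, 0.7, 0.4, 0.3)
  expect_equal(msc(rbind(ref, ref))[1, ], ref, ignore_attr = TRUE)
  row <- 0.5 + 2 * ref
  out <- msc(rbind(row, ref), reference = ref)
  expect_equal(out[1, ], ref, ignore_attr = TRUE, tolerance = 1e-12)

  set.seed(21)
  X <- matrix(runif(24, 0.1, 1), 4, 6)
  got <- msc(X)
  ref2 <- colMeans(X)
  oracle <- t(apply(X, 1, function(x) {
    ab <- solve(rbind(c(length(ref2), sum(ref2)),
                      c(sum(ref2), sum(ref2^2))),
                c(sum(x), sum(x * ref2)))
    (x - ab[1]) / ab[2]
  }))
  expect_equal(unclass(got), oracle, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("row-wise pretreatments commute with sample permutation", {
  set.seed(22)
  X <- matrix(runif(40, 0.1, 1), 5, 8)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(snv(X)[perm, ], snv(X[perm, ]))
  ref <- colMeans(X)
  expect_equal(msc(X, ref)[perm, ], msc(X[perm, ], ref),
               ignore_attr = TRUE)
})

test_that("Savitzky-Golay reproduces polynomials and the classic weights", {
  # window 5, polyorder 2 smoothing weights
  expect_equal(nirsel:::sg_weights(-2:2, 2, 0),
               c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  # a quadratic is reproduced to machine precision, edges included
  x <- seq_len(30)
  row <- 2 + 0.5 * x - 0.03 * x^2
  sm <- savitzky_golay(matrix(row, 1), window = 7, polyorder = 2)
  expect_equal(sm[1, ], row, tolerance = 1e-10)
  # first derivative of a straight line is its slope everywhere
  d1 <- savitzky_golay(matrix(3 * x, 1), window = 7, polyorder = 2,
                       deriv = 1)
  expect_equal(d1[1, ], rep(3, 30), tolerance = 1e-10)
  # derivative scales with the axis spacing
  d2 <- savitzky_golay(matrix(3 * x, 1), window = 7, polyorder = 2,
                       deriv = 1, spacing = 2)
  expect_equal(d2[1, ], rep(1.5, 30), tolerance = 1e-10)
  # constant spectrum is preserved by smoothing
  expect_equal(savitzky_golay(matrix(rep(4, 20), 1), 5, 2)[1, ],
               rep(4, 20))
  expect_error(savitzky_golay(matrix(x, 1), window = 4), "odd")
  expect_error(savitzky_golay(matrix(x, 1), window = 5, polyorder = 5),
               "polyorder")
})

test_that("first_derivative matches the finite-difference oracle", {
  axis <- c(1, 2, 4, 7, 11)
  expect_equal(first_derivative(matrix(3 * axis, 1), axis)[1, ],
               rep(3, 5))
  expect_equal(first_derivative(matrix(rep(2, 5), 1), axis)[1, ],
               rep(0, 5))
  set.seed(23)
  row <- rnorm(5)
  got <- first_derivative(matrix(row, 1), axis)[1, ]
  oracle <- c((row[2] - row[1]) / (axis[2] - axis[1]),
              vapply(2:4, function(i)
                (row[i + 1] - row[i - 1]) / (axis[i + 1] - axis[i - 1]),
                numeric(1)),
              (row[5] - row[4]) / (axis[5] - axis[4]))
  expect_equal(got, oracle)
})

test_that("pretreatment selection minimizes RMSECV with first-wins ties", {
  # classical global multiplicative scatter (no wavelength dependence)
  sim <- make_small_sim(n = 40, p = 60, seed = 3, scatter_sd = 0.15,
                        scatter_harmonics = 0)
  ds <- sim$dataset
  cv <- cv_config("kfold", seed = 7, lv_max = 8)
  one <- select_preprocessing(ds, "cellulose",
                              candidates = list(preprocess_spec("snv")),
                              cv = cv)
  expect_equal(nrow(one$table), 1)
  expect_equal(format(one$best), "snv")
  # identical candidates: the first is returned
  two <- select_preprocessing(ds, "cellulose",
                              candidates = list(preprocess_spec("msc"),
                                                preprocess_spec("msc")),
                              cv = cv)
  expect_equal(two$best_index, 1)
  # under strong multiplicative scatter, MSC beats raw spectra
  comp <- select_preprocessing(ds, "cellulose",
                               candidates = list(preprocess_spec(),
                                                 preprocess_spec("msc")),
                               cv = cv)
  expect_lt(comp$table$rmsecv[2], comp$table$rmsecv[1])
  # failing candidates are recorded, not fatal
  ds2 <- ds
  ds2$X[1, ] <- 1  # constant spectrum breaks SNV
  res <- select_preprocessing(ds2, "cellulose",
                              candidates = list(preprocess_spec("snv"),
                                                preprocess_spec()),
                              cv = cv)
  expect_true(is.na(res$table$rmsecv[1]))
  expect_equal(res$best_index, 2)
})

test_that("frozen MSC reference prevents leakage from new samples", {
  sim <- make_small_sim(n = 30, p = 40, seed = 4)
  X <- sim$dataset$X
  fit <- preprocess_fit(X[1:20, ], preprocess_spec("sg", "msc"),
                        sim$dataset$axis)
  before <- preprocess_apply(fit, X[21:30, ])
  # applying to different new samples must not change the transform itself
  again <- preprocess_apply(fit, X[21:30, ] * 2)
  expect_false(isTRUE(all.equal(before, again)))
  expect_equal(preprocess_apply(fit, X[21:30, ]), before)
})
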
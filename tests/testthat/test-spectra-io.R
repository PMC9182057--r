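test_that("write/read round trip reproduces axis, X, y and ids", {
  set.seed(11)
  ds <- spectra_dataset(c(4000, 4010, 4025, 4030, 4050),
                        matrix(rnorm(15), 3, 5),
                        y = list(cellulose = c(40.1, 45.2, 38.9)),
                        ids = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(ds, path)
  back <- read_spectra_table(path, analytes = "cellulose")
  expect_equal(back$axis, ds$axis)
  expect_equal(back$X, ds$X, tolerance = 1e-12)
  expect_equal(back$y, ds$y, tolerance = 1e-12)
  expect_equal(back$ids, ds$ids)
})

test_that("descending axis is canonicalized to ascending with columns", {
  X <- matrix(1:6, 2, 3)
  ds <- spectra_dataset(c(4020, 4010, 4000), X)
  expect_equal(ds$axis, c(4000, 4010, 4020))
  expect_equal(ds$X, X[, 3:1])
  # tab-separated file with descending headers
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("4020\t4010\t4000\tcell\tid",
               "1\t3\t5\t40\ts1", "2\t4\t6\t41\ts2"), path)
  back <- read_spectra_table(path)
  expect_equal(back$axis, c(4000, 4010, 4020))
  expect_equal(back$X[, 1], c(5, 6))
  expect_equal(names(back$y), "cell")
})

test_that("loader rejects malformed tables with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("4000,4010,cell,id", "1,NA,40,s1"), path)
  expect_error(read_spectra_table(path), "row 1")
  writeLines(c("4000,4010,cell,id", "1,2,40,s1", "3,4,41,s1"), path)
  expect_error(read_spectra_table(path), "duplicate")
  writeLines(c("cell,id", "40,s1"), path)
  expect_error(read_spectra_table(path), "wavenumber")
  expect_error(spectra_dataset(c(1, 2), matrix(c(1, Inf), 1)), "non-finite")
})

test_that("subset_columns keeps order, is idempotent and validates", {
  ds <- spectra_dataset(c(10, 20, 30), matrix(1:9, 3, 3),
                        y = list(a = c(1, 2, 3)))
  full <- subset_columns(ds, 1:3)
  expect_equal(full, ds)
  sub <- subset_columns(ds, c(1, 3))
  expect_equal(sub$axis, c(10, 30))
  expect_equal(ncol(sub$X), 2)
  expect_equal(sub$y, ds$y)
  expect_equal(subset_columns(sub, 1:2), sub)
  expect_error(subset_columns(ds, integer(0)), ">= 1 variable")
  expect_error(subset_columns(ds, 4), "out of range")
})

test_that("JCAMP-DX reader reconstructs axis and scales ordinates", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=toy", "##FIRSTX=0", "##LASTX=4", "##NPOINTS=5",
               "##XFACTOR=1", "##YFACTOR=1",
               "##XYDATA=(X++(Y..Y))", "0 0 1 2", "3 3 4", "##END="), path)
  r <- read_jcamp_single(path)
  expect_equal(r$axis, 0:4)
  expect_equal(r$spectrum, as.numeric(0:4))

  writeLines(c("##TITLE=toy", "##FIRSTX=100", "##LASTX=104", "##NPOINTS=2",
               "##XFACTOR=1", "##YFACTOR=0.5",
               "##XYDATA=(X++(Y..Y))", "100 2 4", "##END="), path)
  r <- read_jcamp_single(path)
  expect_equal(r$spectrum, c(1.0, 2.0))

  # truncated data block must not be a silent short read
  writeLines(c("##TITLE=toy", "##FIRSTX=0", "##LASTX=4", "##NPOINTS=5",
               "##XFACTOR=1", "##YFACTOR=1",
               "##XYDATA=(X++(Y..Y))", "0 0 1 2", "##END="), path)
  expect_error(read_jcamp_single(path), "NPOINTS")
  writeLines(c("##TITLE=toy", "##FIRSTX=0", "##NPOINTS=2", "##XFACTOR=1",
               "##YFACTOR=1", "##XYDATA=(X++(Y..Y))", "0 1 2"), path)
  expect_error(read_jcamp_single(path), "LASTX")
})
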
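test_that("reflectance calibration implements the white/dark formula", {
  expect_equal(calibrate_reflectance(c(0.5), c(0.9), c(0.1)), 0.5)
  # I_o = I_w recovers the panel reflectance; I_o = I_d gives zero
  set.seed(1)
  for (i in 1:5) {
    iw <- runif(20, 0.5, 1); id <- runif(20, 0, 0.2)
    rw <- runif(1, 0.9, 1.1)
    expect_equal(calibrate_reflectance(iw, iw, id, rw), rep(rw, 20))
    expect_equal(calibrate_reflectance(id, iw, id, rw), rep(0, 20))
  }
})

test_that("calibration is scale-equivariant in the panel reflectance", {
  set.seed(2)
  io <- runif(30); iw <- runif(30, 1, 2); id <- runif(30, 0, 0.3)
  r1 <- calibrate_reflectance(io, iw, id, 0.95)
  r2 <- calibrate_reflectance(io, iw, id, 1.9)
  pos <- r1 > 0   # clipped-to-zero entries stay zero under scaling
  expect_equal(r2[pos], 2 * r1[pos])
})

test_that("calibration rejects bad frames with informative errors", {
  expect_error(calibrate_reflectance(1:3, 1:2, 1:3), "equal length")
  expect_error(calibrate_reflectance(c(1, 1), c(2, 5), c(2, 1)),
               "band index 1")
  expect_true(all(calibrate_reflectance(c(-5, 0.5), c(1, 1), c(0, 0)) >= 0))
})

test_that("max-abs normalization scales to unit maximum and is idempotent", {
  expect_equal(max_abs_normalize(c(0, 0, 2)), c(0, 0, 1))
  expect_equal(max_abs_normalize(c(-4, 2)), c(-1, 0.5))
  set.seed(3)
  X <- matrix(runif(50, -1, 2), 5)
  N <- max_abs_normalize(X)
  expect_equal(apply(abs(N), 1, max), rep(1, 5))
  expect_equal(max_abs_normalize(N), N)
  Nb <- max_abs_normalize(X, axis = "band")
  expect_equal(apply(abs(Nb), 2, max), rep(1, 10))
  expect_error(max_abs_normalize(c(0, 0, 0)), "all-zero")
  expect_error(max_abs_normalize(rbind(c(1, 2), c(0, 0))), "row 2")
})

test_that("spectral angle matches hand-computed cases and invariances", {
  expect_equal(spectral_angle(c(1, 0), c(1, 1)), pi / 4)
  expect_equal(spectral_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(spectral_angle(c(1, 0), c(0, 1)), pi / 2)
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(spectral_angle(a, b), spectral_angle(b, a))
    expect_equal(spectral_angle(3.7 * a, b), spectral_angle(a, b))
    expect_gte(spectral_angle(a, b), 0)
    expect_lte(spectral_angle(a, b), pi)
  }
  expect_error(spectral_angle(c(0, 0), c(1, 1)), "zero")
  expect_error(spectral_angle(1:3, 1:4), "equal length")
})

test_that("spectra CSV round-trips with labels, ids and provenance", {
  d <- small_dataset(n = 3, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(d, f)
  d2 <- read_spectra_csv(f)
  expect_equal(d2$spectra, d$spectra, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(d2$psi, d$psi, tolerance = 1e-12)
  expect_equal(d2$sample_ids, d$sample_ids)
  expect_equal(d2$provenance, d$provenance)
})

test_that("CSV reader validates bands and handles units and missing labels", {
  d <- small_dataset(n = 3, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")

  # wrong band count
  short <- d; short$spectra <- d$spectra[, 1:175]; short$grid <- d$grid[1:175]
  class(short) <- "spectra_set"
  write_spectra_csv(short, f)
  expect_error(read_spectra_csv(f), "175 band columns")

  # bar-to-MPa conversion on load
  write_spectra_csv(d, f)
  dbar <- read_spectra_csv(f, unit = "bar")
  expect_equal(dbar$psi, d$psi / 10, tolerance = 1e-12)

  # psi column absent -> unlabelled set
  tab <- utils::read.csv(f, check.names = FALSE)
  utils::write.csv(tab[setdiff(names(tab), "psi_mpa")], f, row.names = FALSE,
                   quote = FALSE)
  unl <- read_spectra_csv(f)
  expect_null(unl$psi)
  expect_equal(dim(unl$spectra), dim(d$spectra))
})

test_that("spectra_set enforces its invariants", {
  m <- matrix(runif(12), 3)
  expect_error(spectra_set(m, grid = c(1, 2, 3)), "does not match")
  expect_error(spectra_set(m, grid = c(4, 3, 2, 1)), "increasing")
  expect_error(spectra_set(m, grid = 1:4, psi = c(0.5, -1, -1)), "<= 0")
  s <- spectra_set(m, grid = 1:4, psi = c(-1, -2, -0.5))
  expect_s3_class(s, "spectra_set")
  expect_equal(dim(s), c(3L, 4L))
  b <- bind_spectra(s, s)
  expect_equal(nrow(b$spectra), 6L)
  expect_error(bind_spectra(s, spectra_set(matrix(1, 1, 3), grid = 1:3)),
               "grids differ|labelled")
})
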
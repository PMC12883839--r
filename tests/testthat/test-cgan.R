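make_train_set <- function(n = 48, seed = 21) {
  d <- generate_dataset(sim_config(n_samples = n, seed = seed))
  d$spectra <- max_abs_normalize(d$spectra)
  d
}

fast_cfg <- function(...) {
  args <- utils::modifyList(
    list(epochs = 5L, batch_size = 16L, gen_hidden = 16L,
         disc_hidden = 16L, noise_dim = 8L, seed = 2L),
    list(...))
  do.call(cgan_config, args)
}

test_that("CGAN training is seeded and records finite loss traces", {
  tr <- make_train_set()
  b1 <- train_cgan(tr, fast_cfg())
  b2 <- train_cgan(tr, fast_cfg())
  expect_identical(b1$gen, b2$gen)
  expect_identical(b1$disc, b2$disc)
  expect_length(b1$loss_trace$generator, 5L)
  expect_true(all(is.finite(b1$loss_trace$generator)))
  expect_true(all(is.finite(b1$loss_trace$discriminator)))
})

test_that("CGAN training rejects unlabelled or too-small sets", {
  tr <- make_train_set()
  unl <- tr; unl$psi <- NULL
  expect_error(train_cgan(unl, fast_cfg()), "labelled")
  expect_error(train_cgan(tr, fast_cfg(batch_size = 100L)),
               "smaller batch_size")
})

test_that("condition grids are evenly spaced with endpoints included", {
  expect_equal(resample_condition_grid(5, -1, 0),
               c(-1, -0.75, -0.5, -0.25, 0))
  g <- resample_condition_grid(500, -2.3, -0.2)
  expect_length(g, 500L)
  expect_equal(g[1], -2.3); expect_equal(g[500], -0.2)
  expect_equal(diff(g), rep(diff(g)[1], 499))
  set.seed(1)
  r <- resample_condition_grid(100, -2, -0.5, random = TRUE)
  expect_true(all(r >= -2 & r <= -0.5))
  expect_error(resample_condition_grid(5, 0, -1), "psi_min")
  expect_error(resample_condition_grid(1, -1, 0), "n must be")
})

test_that("conditioned generation is seeded, labelled and condition-aware", {
  tr <- make_train_set()
  b <- train_cgan(tr, fast_cfg())
  conds <- resample_condition_grid(20, min(tr$psi), max(tr$psi))
  g1 <- generate_conditioned_spectra(b, conds, seed = 5)
  g2 <- generate_conditioned_spectra(b, conds, seed = 5)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$spectra), 20L)
  expect_equal(g1$psi, conds)
  expect_true(all(g1$provenance == "cgan_generated"))
  expect_true(all(g1$spectra >= 0))
  # same noise, different conditions -> different spectra
  ga <- generate_conditioned_spectra(b, rep(-0.3, 4), seed = 7)
  gb <- generate_conditioned_spectra(b, rep(-2.2, 4), seed = 7)
  expect_gt(max(abs(ga$spectra - gb$spectra)), 1e-8)
  # untrained bundles refuse to generate unless explicitly allowed
  b0 <- train_cgan(tr, fast_cfg(epochs = 0L))
  expect_error(generate_conditioned_spectra(b0, conds), "untrained")
  g0 <- generate_conditioned_spectra(b0, conds, allow_untrained = TRUE)
  expect_equal(nrow(g0$spectra), 20L)
})

test_that("SAM fidelity compares column-mean spectra", {
  tr <- make_train_set()
  expect_equal(fidelity_sam(tr, tr), 0)
  scaled <- tr; scaled$spectra <- 0.5 * tr$spectra
  expect_equal(fidelity_sam(tr, scaled), 0, tolerance = 1e-12)
  a <- toy_set(rbind(c(2, 0, 0), c(0, 0, 0)))
  b <- toy_set(rbind(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(fidelity_sam(a, b), pi / 4)
  short <- toy_set(matrix(1, 2, 4))
  expect_error(fidelity_sam(tr, short), "grids differ")
})

test_that("augmentation appends flagged synthetic rows without mutation", {
  tr <- make_train_set()
  before <- tr
  b <- train_cgan(tr, fast_cfg(n_synthetic = 30L))
  aug <- augment_training_set(tr, b, seed = 3)
  expect_identical(tr, before)           # pure function
  expect_equal(nrow(aug$spectra), 48L + 30L)
  expect_equal(sum(aug$provenance == "cgan_generated"), 30L)
  expect_equal(sum(aug$provenance == "measured"), 48L)
  expect_true(all(aug$psi[aug$provenance == "cgan_generated"] >= min(tr$psi)))
  none <- augment_training_set(tr, b, cgan_config(n_synthetic = 0L))
  expect_identical(none, tr)
})
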
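# Shared fixtures, built in code at test time.

# Small labelled dataset on the full 176-band grid.
small_dataset <- function(n = 60, seed = 3, noiseless = FALSE) {
  cfg <- if (noiseless)
    sim_config(n_samples = n, seed = seed, noise_sd_additive = 0,
               noise_sd_multiplicative = 0, structural_sd = 0)
  else sim_config(n_samples = n, seed = seed)
  generate_dataset(cfg)
}

# Tiny extractor configuration for fast structural tests.
tiny_irac <- function(...) {
  irac_config(n_bands = 24L, channels = 4L, ...)
}

# A toy spectra_set on a short grid.
toy_set <- function(mat, psi = NULL) {
  spectra_set(mat, grid = seq(400, 400 + 10 * (ncol(mat) - 1),
                              length.out = ncol(mat)),
              psi = psi)
}
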
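#' Simulator configuration
#'
#' Parameters of the seeded leaf-spectra simulator. Defaults emulate the
#' dehydration-experiment study design the package targets: 229 samples,
#' leaf water potential between -2.5 and -0.1 MPa with mean about -1 MPa and
#' few samples at strongly negative values, vegetation-shaped reflectance,
#' and a near-infrared plateau that rises as water potential falls.
#'
#' @param n_samples Number of spectra (default 229).
#' @param seed Integer seed; the full simulation is deterministic given it.
#' @param psi_range_mpa Length-2 range (lo, hi) of psi in MPa, both negative.
#' @param imbalance_shape Beta shape parameters (a, b) of the psi sampling
#'   law; psi = hi - (hi - lo) * Beta(a, b), so mass concentrates near mild
#'   stress and thins toward the dry end. Default c(2, 10/3) puts the mean
#'   at -1.0 MPa on the default range.
#' @param noise_sd_additive SD of additive (sensor) Gaussian noise per band.
#' @param noise_sd_multiplicative SD of multiplicative (gain) Gaussian noise.
#' @param structural_sd Scale of per-leaf structural variability unrelated
#'   to psi: an overall brightness gain (dominant, as leaf pose and
#'   illumination mostly rescale the whole spectrum) plus small independent
#'   perturbations of the visible baseline, chlorophyll-dip depth and
#'   plateau level; 0 makes the psi-to-spectrum map deterministic and
#'   injective.
#' @param nir_sensitivity Increase of the NIR plateau reflectance per MPa of
#'   psi decline (unitless reflectance per MPa).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 229L, seed = 1L,
                       psi_range_mpa = c(-2.5, -0.1),
                       imbalance_shape = c(2, 10 / 3),
                       noise_sd_additive = 0.005,
                       noise_sd_multiplicative = 0.02,
                       structural_sd = 1,
                       nir_sensitivity = 0.10) {
  stopifnot(n_samples >= 2, length(psi_range_mpa) == 2,
            all(psi_range_mpa < 0), psi_range_mpa[1] < psi_range_mpa[2],
            all(imbalance_shape > 0), noise_sd_additive >= 0,
            noise_sd_multiplicative >= 0, structural_sd >= 0,
            nir_sensitivity >= 0)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 psi_range_mpa = psi_range_mpa,
                 imbalance_shape = imbalance_shape,
                 noise_sd_additive = noise_sd_additive,
                 noise_sd_multiplicative = noise_sd_multiplicative,
                 structural_sd = structural_sd,
                 nir_sensitivity = nir_sensitivity),
            class = "sim_config")
}

#' Draw leaf water potential values
#'
#' Samples psi from a right-skewed scaled Beta law on the configured range:
#' density is concentrated near mild stress and thins toward the most
#' negative values, reflecting that pressure-chamber measurements are hard
#' to obtain late in dehydration.
#'
#' @param cfg A \code{sim_config}.
#' @param n Number of draws (default \code{cfg$n_samples}).
#' @return Numeric vector of psi values in MPa, inside the configured range.
#' @export
sample_psi_values <- function(cfg = sim_config(), n = cfg$n_samples) {
  lo <- cfg$psi_range_mpa[1]; hi <- cfg$psi_range_mpa[2]
  if (hi - lo <= 0) stop("degenerate psi range")
  set.seed(cfg$seed)
  b <- stats::rbeta(n, cfg$imbalance_shape[1], cfg$imbalance_shape[2])
  hi - (hi - lo) * b
}

# Noiseless vegetation reflectance template on a wavelength grid:
# low visible baseline, Gaussian chlorophyll absorption dip at 680 nm,
# logistic red-edge rise across 700-750 nm, flat NIR plateau after ~900 nm
# whose level rises with water stress (-psi).
spectrum_template <- function(psi, grid, nir_sensitivity,
                              vis = 0.08, dip_depth = 0.045,
                              plateau_base = 0.42) {
  plateau <- plateau_base + nir_sensitivity * (-psi)
  r <- vis + (plateau - vis) / (1 + exp(-(grid - 725) / 12))
  r - dip_depth * exp(-(grid - 680)^2 / (2 * 15^2))
}

#' Map a water potential to a reflectance spectrum
#'
#' Deterministic vegetation template plus the psi effect on the NIR plateau,
#' then per-leaf structural variability and multiplicative/additive Gaussian
#' noise as configured; output clipped to [0, 1.2]. With all noise and
#' structural SDs at 0 the map is deterministic and injective in psi.
#'
#' @param psi Leaf water potential, MPa, inside \code{cfg$psi_range_mpa}.
#' @param cfg A \code{sim_config}.
#' @param grid Wavelength grid (nm).
#' @return Numeric reflectance vector of length \code{length(grid)}.
#' @export
psi_to_spectrum <- function(psi, cfg = sim_config(),
                            grid = default_wavelength_grid()) {
  lo <- cfg$psi_range_mpa[1]; hi <- cfg$psi_range_mpa[2]
  if (psi < lo - 1e-9 || psi > hi + 1e-9)
    stop("psi ", psi, " outside configured range [", lo, ", ", hi, "]")
  s <- cfg$structural_sd
  vis <- 0.08 + s * stats::rnorm(1, 0, 0.005)
  dip <- 0.045 + s * stats::rnorm(1, 0, 0.008)
  pb <- 0.42 + s * stats::rnorm(1, 0, 0.010)
  leaf_gain <- 1 + s * stats::rnorm(1, 0, 0.05)
  r <- leaf_gain * spectrum_template(psi, grid, cfg$nir_sensitivity,
                                     vis = vis, dip_depth = dip,
                                     plateau_base = pb)
  gain <- 1 + stats::rnorm(length(grid), 0, cfg$noise_sd_multiplicative)
  r <- r * gain + stats::rnorm(length(grid), 0, cfg$noise_sd_additive)
  pmin(pmax(r, 0), 1.2)
}

#' Generate a labelled synthetic dataset
#'
#' Draws psi values and the corresponding noisy spectra; fully deterministic
#' given the config (including its seed).
#'
#' @param cfg A \code{sim_config}.
#' @param grid Wavelength grid (nm).
#' @return A labelled \code{spectra_set} with provenance "measured".
#' @export
#' @examples
#' d <- generate_dataset(sim_config(n_samples = 20, seed = 1))
#' dim(d)
generate_dataset <- function(cfg = sim_config(),
                             grid = default_wavelength_grid()) {
  psi <- sample_psi_values(cfg)
  mat <- matrix(0, cfg$n_samples, length(grid))
  for (i in seq_len(cfg$n_samples))
    mat[i, ] <- psi_to_spectrum(psi[i], cfg, grid)
  spectra_set(mat, grid = grid, psi = psi, provenance = "measured")
}
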
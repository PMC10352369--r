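## Silicon drift detector response: full-energy-peak efficiency, Fano-noise
## energy resolution, Gaussian binning of transport events into spectra.

#' Detector response model
#'
#' @param thickness_mm Sensor thickness in mm.
#' @param noise_fwhm_eV Electronic noise FWHM in eV.
#' @param fano Fano factor of the sensor material.
#' @param pair_eV Electron-hole pair creation energy in eV.
#' @param edges_keV Energy bin edges in keV (strictly increasing).
#' @param material Sensor [xfi_material]; default silicon.
#' @return An object of class `xfi_detmodel`.
#' @examples
#' m <- detector_model()
#' full_energy_efficiency(m, 44)   # ~0.04
#' resolution_fwhm(m, 28.6)        # ~0.29 keV
#' @export
detector_model <- function(thickness_mm = 0.5, noise_fwhm_eV = 120,
                           fano = 0.115, pair_eV = 3.85,
                           edges_keV = seq(0, 60, by = 0.05),
                           material = builtin_material("silicon")) {
  stopifnot(thickness_mm > 0, all(diff(edges_keV) > 0))
  structure(list(thickness_mm = thickness_mm, noise_fwhm_eV = noise_fwhm_eV,
                 fano = fano, pair_eV = pair_eV,
                 edges_keV = edges_keV, material = material),
            class = "xfi_detmodel")
}

#' Full-energy-peak efficiency
#'
#' Probability that an incident photon is photoelectrically absorbed in the
#' sensor, i.e. deposits its full energy: `1 - exp(-tau/rho * rho * t)`.
#' Compton interactions in the thin sensor deposit only partial energy and
#' are not counted toward the full-energy peak.
#'
#' @param model An [detector_model()].
#' @param E Photon energy in keV (vectorized).
#' @return Absorption probability in `[0, 1]`.
#' @export
full_energy_efficiency <- function(model, E) {
  tau <- mu_over_rho(model$material, E, "photoelectric")
  1 - exp(-tau * model$material$density * model$thickness_mm * 0.1)
}

#' Detector energy resolution
#'
#' Gaussian FWHM combining Fano statistics and electronic noise:
#' `2.355 * sqrt(F * eps * E + sigma_noise^2)`.
#'
#' @param model An [detector_model()].
#' @param E Photon energy in keV (vectorized); `E = 0` gives the electronic
#'   noise floor.
#' @return FWHM in keV.
#' @export
resolution_fwhm <- function(model, E) {
  sig_noise_eV <- model$noise_fwhm_eV / 2.3548200
  var_eV2 <- model$fano * model$pair_eV * E * 1000 + sig_noise_eV^2
  2.3548200 * sqrt(var_eV2) / 1000
}

#' Binned spectrum container
#'
#' @param edges_keV Bin edges (length n+1).
#' @param counts Counts per bin (length n, non-negative).
#' @param livetime_s Acquisition livetime in seconds.
#' @param meta Named list of metadata (pixel position, seed, geometry, ...).
#' @return An object of class `xfi_spectrum`.
#' @export
xfi_spectrum <- function(edges_keV, counts, livetime_s = 1, meta = list()) {
  stopifnot(length(counts) == length(edges_keV) - 1, all(counts >= 0),
            all(diff(edges_keV) > 0))
  structure(list(edges_keV = edges_keV, counts = counts,
                 livetime_s = livetime_s, meta = meta),
            class = "xfi_spectrum")
}

#' @export
print.xfi_spectrum <- function(x, ...) {
  cat(sprintf(
    "<xfi_spectrum> %d bins [%.3g, %.3g] keV, %.4g counts, livetime %.3g s\n",
    length(x$counts), min(x$edges_keV), max(x$edges_keV), sum(x$counts),
    x$livetime_s))
  invisible(x)
}

#' Bin centers of a spectrum
#' @param spectrum An `xfi_spectrum`.
#' @return Numeric vector of bin centers in keV.
#' @export
bin_centers <- function(spectrum) {
  e <- spectrum$edges_keV
  (e[-1] + e[-length(e)]) / 2
}

#' Apply the detector response to transport events
#'
#' Each detected event contributes `weight * efficiency(E)` counts, spread
#' over the energy bins as a Gaussian of the model's FWHM at E, and scaled
#' to physical counts with the transport scale factor (flux x area x dwell /
#' primaries).  The result is the expected (noise-free) measured spectrum;
#' see [add_counting_noise()] for Poisson sampling.
#'
#' @param model An [detector_model()].
#' @param result An [run_position()] result.
#' @return An `xfi_spectrum` with livetime equal to the beam dwell time.
#' @export
apply_response <- function(model, result) {
  stopifnot(inherits(model, "xfi_detmodel"),
            inherits(result, "xfi_transport"))
  ev <- result$events
  eff <- full_energy_efficiency(model, ev$energy_keV)
  sig <- resolution_fwhm(model, ev$energy_keV) / 2.3548200
  counts <- cpp_bin_gaussian(ev$energy_keV, ev$weight * eff * result$scale,
                             sig, model$edges_keV)
  xfi_spectrum(model$edges_keV, counts,
               livetime_s = result$beam$dwell_s,
               meta = list(pixel_y = result$center_yz[1],
                           pixel_z = result$center_yz[2],
                           seed = result$seed,
                           n_primaries = result$n_primaries,
                           beam_energy_keV = result$beam$energy_keV,
                           transmitted_fraction =
                             result$transmitted_fraction))
}

#' Add Poisson counting noise to an expected spectrum
#'
#' @param spectrum An `xfi_spectrum` of expected counts.
#' @param seed Optional seed for reproducibility.
#' @return An `xfi_spectrum` with integer Poisson-sampled counts.
#' @export
add_counting_noise <- function(spectrum, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  noisy <- spectrum
  noisy$counts <- stats::rpois(length(spectrum$counts), spectrum$counts)
  noisy
}
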
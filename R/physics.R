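## Core photon physics: Compton kinematics, Klein-Nishina cross sections,
## attenuation-coefficient lookups and fluorescence production.

.MEC2 <- 511.0          # electron rest energy, keV
.RE2 <- 7.940787e-26    # classical electron radius squared, cm^2
.NA_BARN <- 0.60221408  # sigma[b] * (Z/A) -> cm^2/g conversion factor

#' Compton-scattered photon energy
#'
#' Energy of a photon of energy `E0` after inelastic scattering through polar
#' angle `theta` on a free electron at rest.
#'
#' @param E0 Incident photon energy in keV.
#' @param theta Scattering angle in radians, in `[0, pi]`.
#' @return Scattered photon energy in keV (vectorized over both arguments).
#' @examples
#' compton_energy(53, 150 * pi / 180) # ~44.4 keV
#' @export
compton_energy <- function(E0, theta) {
  if (any(E0 <= 0)) stop("E0 must be positive", call. = FALSE)
  if (any(theta < 0 | theta > pi + 1e-12)) {
    stop("theta must lie in [0, pi]", call. = FALSE)
  }
  E0 / (1 + (E0 / .MEC2) * (1 - cos(theta)))
}

#' Klein-Nishina differential cross section
#'
#' Free-electron differential Compton cross section per unit solid angle.
#' For an unpolarized beam the azimuth is uniform; with `polarization`
#' in (0, 1] and azimuth `phi` measured from the polarization axis, the
#' standard azimuthal modulation is applied.
#'
#' @param E0 Incident photon energy in keV.
#' @param theta Polar scattering angle in radians.
#' @param phi Azimuthal angle in radians (only used when `polarization > 0`).
#' @param polarization Degree of linear polarization in `[0, 1]`; default 0
#'   (unpolarized).
#' @return Differential cross section in cm^2/sr per electron.
#' @examples
#' klein_nishina_dcs(53, 0) # Thomson forward value ~7.94e-26
#' @export
klein_nishina_dcs <- function(E0, theta, phi = 0, polarization = 0) {
  if (any(E0 <= 0)) stop("E0 must be positive", call. = FALSE)
  k <- E0 / .MEC2
  r <- 1 / (1 + k * (1 - cos(theta)))  # E'/E0
  unpol <- 0.5 * .RE2 * r^2 * (r + 1 / r - sin(theta)^2)
  if (all(polarization == 0)) {
    return(unpol)
  }
  # polarized: sin^2(theta) cos^2(phi) term replaces the averaged sin^2/2
  pol <- 0.5 * .RE2 * r^2 *
    (r + 1 / r - 2 * sin(theta)^2 * cos(phi)^2)
  (1 - polarization) * unpol + polarization * pol
}

#' Total Klein-Nishina cross section
#'
#' Closed-form total free-electron Compton cross section.
#'
#' @param E0 Incident photon energy in keV.
#' @return Total cross section in cm^2 per electron.
#' @export
kn_total_xs <- function(E0) {
  if (any(E0 <= 0)) stop("E0 must be positive", call. = FALSE)
  k <- E0 / .MEC2
  2 * pi * .RE2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

#' Sample Compton scattering angles
#'
#' Draws polar scattering angles from the Klein-Nishina distribution
#' (density proportional to the differential cross section times
#' sin(theta)) by rejection sampling.  Uses R's random number stream, so
#' results are reproducible under [set.seed()].
#'
#' @param E0 Incident photon energy in keV (scalar).
#' @param n Number of samples.
#' @return Numeric vector of angles in radians.
#' @examples
#' set.seed(1)
#' th <- sample_compton_angle(53, 1000)
#' @export
sample_compton_angle <- function(E0, n = 1) {
  if (length(E0) != 1 || E0 <= 0) {
    stop("E0 must be a positive scalar", call. = FALSE)
  }
  cpp_sample_compton(E0, as.integer(n))
}

.PROCESSES <- c("photoelectric", "incoherent", "coherent", "total",
                "energy_absorption")

.mu_element <- function(symbol, E, process) {
  tab <- .attenuation_raw(symbol)
  rng <- range(tab$energy_keV)
  if (any(E < rng[1] - 1e-9 | E > rng[2] + 1e-9)) {
    stop(sprintf("energy outside table grid [%.4g, %.4g] keV for %s",
                 rng[1], rng[2], symbol), call. = FALSE)
  }
  exp(stats::approx(log(tab$energy_keV), log(tab[[process]]), log(E),
                    rule = 2, ties = "ordered")$y)
}

#' Mass attenuation coefficient
#'
#' Looks up the mass attenuation coefficient of an element or material at
#' energy `E`, log-log interpolated on the shipped cross-section grid
#' (1-100 keV).  Material coefficients are mass-fraction-weighted sums of
#' the elemental ones.
#'
#' @param target Element symbol (e.g. `"Si"`) or an [xfi_material].
#' @param E Photon energy in keV (vectorized).
#' @param process One of `"photoelectric"`, `"incoherent"`, `"coherent"`,
#'   `"total"`, `"energy_absorption"`.
#' @return Coefficient in cm^2/g.
#' @examples
#' mu_over_rho(builtin_material("water"), 30, "total") # ~0.376
#' @export
mu_over_rho <- function(target, E, process = "total") {
  process <- match.arg(process, .PROCESSES)
  if (inherits(target, "xfi_material")) {
    vals <- vapply(names(target$fractions),
                   function(s) .mu_element(s, E, process) *
                     target$fractions[[s]],
                   numeric(length(E)))
    if (length(E) == 1) sum(vals) else rowSums(matrix(vals, nrow = length(E)))
  } else if (is.character(target) && length(target) == 1) {
    .mu_element(target, E, process)
  } else {
    stop("target must be an element symbol or an xfi_material",
         call. = FALSE)
  }
}

#' Fluorescence production cross section
#'
#' Mass cross section for producing a given K emission line of an element
#' under excitation at `E0`: the K-shell share of the photoelectric
#' coefficient (via the absorption jump factor, `1 - 1/J_K`), times the K
#' fluorescence yield, times the line's relative intensity.
#'
#' @param element An [element_data()] object or element symbol.
#' @param line Line label (`"Ka1"`, `"Ka2"`, `"Kb1"`) or `"Ka"`/`"K"` for the
#'   summed alpha doublet / full K series.
#' @param E0 Excitation energy in keV; must exceed the K edge.
#' @return Cross section in cm^2/g of the element.
#' @examples
#' fluorescence_production_xs("I", "Ka1", 53)
#' @export
fluorescence_production_xs <- function(element, line, E0) {
  el <- if (inherits(element, "xfi_element")) element else element_data(element)
  if (is.null(el$lines)) {
    stop("element '", el$symbol, "' has no tabulated K lines", call. = FALSE)
  }
  if (any(E0 <= el$k_edge_keV)) {
    stop(sprintf("excitation energy %.4g keV is below the %s K edge (%.4g keV)",
                 min(E0), el$symbol, el$k_edge_keV), call. = FALSE)
  }
  frac <- if (line %in% c("K", "all")) {
    1
  } else if (line == "Ka") {
    sum(el$lines$rel_intensity[el$lines$line %in% c("Ka1", "Ka2")])
  } else {
    f <- el$lines$rel_intensity[el$lines$line == line]
    if (length(f) == 0) stop("unknown line '", line, "'", call. = FALSE)
    f
  }
  tau <- .mu_element(el$symbol, E0, "photoelectric")
  tau * (1 - 1 / el$k_jump) * el$omega_k * frac
}

#' Minimum number of Compton scatters to reach an energy
#'
#' The smallest number of scatters n such that iterating the maximal
#' single-scatter (180 degree) energy loss n times on `E0` yields an energy
#' at or below `E_target`.  This is the kinematic floor behind the high
#' Compton multiplicity of the spectral background in the fluorescence
#' signal window.
#'
#' @param E0 Starting photon energy in keV.
#' @param E_target Target energy in keV, `0 < E_target <= E0`.
#' @return Integer scatter count.
#' @examples
#' min_compton_scatters(53, 28.61) # 5
#' @export
min_compton_scatters <- function(E0, E_target) {
  if (E0 <= 0 || E_target <= 0) stop("energies must be positive",
                                     call. = FALSE)
  if (E_target > E0) stop("E_target must not exceed E0", call. = FALSE)
  n <- 0L
  E <- E0
  while (E > E_target) {
    E <- E / (1 + 2 * E / .MEC2)
    n <- n + 1L
  }
  n
}
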
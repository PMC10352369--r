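## Local energy dose per scan position (kerma approximation) and the
## compliance check against the cell-survival dose limit.

#' Local energy dose per scan position
#'
#' Kerma estimate at a given depth in the body material: photon fluence of
#' one scan position times photon energy times the mass energy-absorption
#' coefficient, attenuated to depth.  In continuous-scan mode the beam
#' sweeps a travel length per recorded position, so the photons of one
#' position are spread over `(width + travel) x height`; `travel_mm = 0`
#' recovers the static (step-scan) footprint normalization.
#'
#' @param beam An [beam_spec()].
#' @param material Body [xfi_material] (default water).
#' @param depth_mm Depth below the surface in mm.
#' @param travel_mm Scan travel per recorded position in mm (default 1, the
#'   continuous-scan raster pitch; the beam width rides along y).
#' @return An object of class `xfi_dose` with the dose in mGy and the
#'   parameters used.
#' @examples
#' b <- beam_spec(53, width_mm = 0.1, height_mm = 1, dwell_s = 0.75)
#' local_dose(b)  # on the order of 200 mGy
#' @export
local_dose <- function(beam, material = builtin_material("water"),
                       depth_mm = 0, travel_mm = 1.0) {
  stopifnot(inherits(beam, "xfi_beam"), depth_mm >= 0, travel_mm >= 0)
  n_ph <- beam$flux_per_s_mm2 * beam$width_mm * beam$height_mm *
    beam$dwell_s
  exposed_mm2 <- (beam$width_mm + travel_mm) * beam$height_mm
  fluence_cm2 <- n_ph / exposed_mm2 * 100
  E_J <- beam$energy_keV * 1.602177e-16
  mu_en <- mu_over_rho(material, beam$energy_keV, "energy_absorption")
  atten <- exp(-mu_over_rho(material, beam$energy_keV, "total") *
                 material$density * depth_mm * 0.1)
  dose_mGy <- fluence_cm2 * E_J * mu_en * 1000 * atten * 1000
  structure(list(dose_mGy = dose_mGy,
                 params = list(energy_keV = beam$energy_keV,
                               flux_per_s_mm2 = beam$flux_per_s_mm2,
                               footprint_mm2 = beam$width_mm * beam$height_mm,
                               dwell_s = beam$dwell_s,
                               travel_mm = travel_mm,
                               depth_mm = depth_mm,
                               material = material$name)),
            class = "xfi_dose")
}

#' @export
print.xfi_dose <- function(x, ...) {
  cat(sprintf("<xfi_dose> %.4g mGy at depth %g mm (%s)\n", x$dose_mGy,
              x$params$depth_mm, x$params$material))
  invisible(x)
}

#' Check a dose report against a limit
#'
#' @param report An [local_dose()] result (or a plain dose in mGy).
#' @param limit_mGy Dose limit in mGy (default 300, the level below which
#'   irradiated T cells can repair radiation damage).
#' @return `TRUE` iff the dose does not exceed the limit.
#' @examples
#' check_limit(local_dose(beam_spec(dwell_s = 0.1)))
#' @export
check_limit <- function(report, limit_mGy = 300) {
  dose <- if (inherits(report, "xfi_dose")) report$dose_mGy else report
  dose <= limit_mGy
}
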
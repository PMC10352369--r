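## R-side interface to the Monte-Carlo engine: beam/detector descriptions,
## single-position runs, raster scans, and multiplicity summaries.

#' Pencil-beam description
#'
#' @param energy_keV Mean photon energy in keV.
#' @param bandwidth_fwhm_keV Gaussian bandwidth FWHM in keV; 0 means
#'   monochromatic.
#' @param width_mm,height_mm Beam footprint in mm (width along y, height
#'   along z).
#' @param flux_per_s_mm2 Unattenuated flux density in photons/s per 1x1 mm^2.
#' @param dwell_s Dwell time per scan position in seconds.
#' @param polarization Degree of linear polarization in `[0, 1]` along the
#'   horizontal (y) axis; default 0 (unpolarized).
#' @return An object of class `xfi_beam`.
#' @examples
#' beam_spec(53, 0, width_mm = 0.1, height_mm = 1, dwell_s = 0.75)
#' @export
beam_spec <- function(energy_keV = 53, bandwidth_fwhm_keV = 0,
                      width_mm = 1, height_mm = 1,
                      flux_per_s_mm2 = 8e10, dwell_s = 1,
                      polarization = 0) {
  stopifnot(energy_keV > 0, bandwidth_fwhm_keV >= 0, flux_per_s_mm2 >= 0,
            width_mm > 0, height_mm > 0, dwell_s >= 0,
            polarization >= 0, polarization <= 1)
  structure(list(energy_keV = energy_keV,
                 bandwidth_fwhm_keV = bandwidth_fwhm_keV,
                 width_mm = width_mm, height_mm = height_mm,
                 flux_per_s_mm2 = flux_per_s_mm2, dwell_s = dwell_s,
                 polarization = polarization),
            class = "xfi_beam")
}

#' Fluorescence detector geometry
#'
#' The detector is modelled as a collimated aperture at a polar angle from
#' the beam axis in the x-y plane, at a fixed distance from the beam axis
#' point of the current scan position (beam and detector are fixed in the
#' lab; the object is translated).
#'
#' @param angle_deg Detection angle from the incident beam direction.
#' @param distance_mm Distance from the beam axis point at x = 0.
#' @param area_mm2 Collimated active area.
#' @return An object of class `xfi_detgeom`.
#' @export
detector_geometry <- function(angle_deg = 150, distance_mm = 57,
                              area_mm2 = 50) {
  stopifnot(distance_mm > 0, area_mm2 > 0)
  structure(list(angle_deg = angle_deg, distance_mm = distance_mm,
                 area_mm2 = area_mm2),
            class = "xfi_detgeom")
}

.det_position <- function(det, center_yz = c(0, 0)) {
  a <- det$angle_deg * pi / 180
  c(det$distance_mm * cos(a),
    center_yz[1] + det$distance_mm * sin(a),
    center_yz[2])
}

#' Detector solid angle
#'
#' Point-detector solid angle `area / distance^2` in steradians.
#'
#' @param det An [detector_geometry()].
#' @return Solid angle in sr.
#' @export
solid_angle <- function(det) det$area_mm2 / det$distance_mm^2

.marker_line_registry <- function(elements) {
  reg <- list()
  decode <- data.frame(code = 0L, label = "scatter",
                       stringsAsFactors = FALSE)
  for (i in seq_along(elements)) {
    el <- element_data(elements[i])
    codes <- as.integer((i - 1) * 10 + seq_len(nrow(el$lines)))
    reg[[i]] <- list(element = el, codes = codes)
    decode <- rbind(decode, data.frame(
      code = codes,
      label = paste0("fluorescence:", el$symbol, ":", el$lines$line),
      stringsAsFactors = FALSE))
  }
  list(reg = reg, decode = decode)
}

.engine_grid <- function(symbols) {
  E <- unlist(lapply(symbols, function(s) .attenuation_raw(s)$energy_keV))
  sort(unique(E))
}

.engine_args <- function(phantom, beam, det, center_yz, cutoff) {
  mat <- phantom$material
  marker_syms <- unique(vapply(phantom$deposits, `[[`, "", "element"))
  grid <- .engine_grid(c(names(mat$fractions), marker_syms))
  lin <- function(proc) {
    mu_over_rho(mat, grid, proc) * mat$density * 0.1  # per mm
  }
  body <- list(radius = phantom$diameter_mm / 2,
               half_length = phantom$length_mm / 2,
               grid_keV = grid,
               mu_photo = lin("photoelectric"),
               mu_inc = lin("incoherent"),
               mu_coh = lin("coherent"))
  regs <- .marker_line_registry(marker_syms)
  markers <- lapply(seq_along(marker_syms), function(i) {
    el <- regs$reg[[i]]$element
    list(photo = .mu_element(el$symbol, grid, "photoelectric"),
         inc = .mu_element(el$symbol, grid, "incoherent"),
         coh = .mu_element(el$symbol, grid, "coherent"),
         k_edge = el$k_edge_keV, omega_k = el$omega_k, jump = el$k_jump,
         line_E = el$lines$energy_keV, line_frac = el$lines$rel_intensity,
         line_code = regs$reg[[i]]$codes)
  })
  dep_mat <- if (length(phantom$deposits)) {
    t(vapply(phantom$deposits, function(d) {
      c(ifelse(d$shape == "sphere", 0, 1), d$center,
        if (d$shape == "sphere") c(d$radius_mm, 0, 0) else d$extents_mm,
        match(d$element, marker_syms) - 1,
        d$conc_ug_mm3 * 1e-3)  # ug/mm^3 -> g/cm^3
    }, numeric(9)))
  } else {
    matrix(numeric(0), ncol = 9)
  }
  beam_l <- list(energy = beam$energy_keV,
                 sigma = beam$bandwidth_fwhm_keV / 2.3548200,
                 yc = center_yz[1], zc = center_yz[2],
                 width = beam$width_mm, height = beam$height_mm,
                 x_start = -(phantom$diameter_mm / 2 + 50))
  det_l <- list(position = .det_position(det, center_yz),
                area = det$area_mm2)
  list(body = body, markers = markers, deposits = dep_mat,
       beam = beam_l, detector = det_l, decode = regs$decode)
}

#' Run Monte-Carlo transport for one scan position
#'
#' Simulates `n_primaries` beam photons through the phantom and returns the
#' list of (weighted) photon events reaching the detector, tagged with their
#' Compton-scatter multiplicity and origin (bulk scatter or a specific
#' fluorescence line).
#'
#' @param phantom An [make_mouse_phantom()] phantom.
#' @param beam An [beam_spec()].
#' @param det An [detector_geometry()].
#' @param n_primaries Number of primary photons (>= 1).
#' @param seed Integer seed; the run is reproducible given the same seed.
#' @param center_yz Beam axis position `c(y, z)` in mm.
#' @param forced Use forced-detection variance reduction (default) or fully
#'   analog transport with an aperture-crossing detector.
#' @param coherent Include coherent (Rayleigh) scattering as a transport
#'   process.
#' @param cutoff_keV Photon termination energy.
#' @return An object of class `xfi_transport` with elements `events` (data
#'   frame: `energy_keV`, `multiplicity`, `origin`, `weight`),
#'   `n_primaries`, `scale` (physical photons represented per unit event
#'   weight), `transmitted_fraction`, and the run metadata.
#' @examples
#' ph <- make_mouse_phantom()
#' tr <- run_position(ph, beam_spec(dwell_s = 0.1), detector_geometry(),
#'                    n_primaries = 1000, seed = 1)
#' @export
run_position <- function(phantom, beam, det, n_primaries, seed = 1,
                         center_yz = c(0, 0), forced = TRUE,
                         coherent = FALSE, cutoff_keV = 15) {
  stopifnot(inherits(phantom, "xfi_phantom"), inherits(beam, "xfi_beam"),
            inherits(det, "xfi_detgeom"))
  if (n_primaries < 1) stop("n_primaries must be >= 1", call. = FALSE)
  args <- .engine_args(phantom, beam, det, center_yz, cutoff_keV)
  opts <- list(n_primaries = as.integer(n_primaries), cutoff = cutoff_keV,
               forced = forced, coherent = coherent,
               polarization = beam$polarization)
  set.seed(as.integer(seed %% .Machine$integer.max))
  raw <- cpp_run_position(args$body, args$markers, args$deposits,
                          args$beam, args$detector, opts)
  origin <- factor(args$decode$label[match(raw$origin, args$decode$code)],
                   levels = args$decode$label)
  events <- data.frame(energy_keV = raw$energy,
                       multiplicity = raw$multiplicity,
                       origin = origin,
                       weight = raw$weight)
  structure(list(events = events,
                 n_primaries = raw$n_primaries,
                 scale = beam$flux_per_s_mm2 * beam$width_mm *
                   beam$height_mm * beam$dwell_s / raw$n_primaries,
                 transmitted_fraction = raw$transmitted_fraction,
                 beam = beam, det = det, center_yz = center_yz,
                 seed = seed, forced = forced, coherent = coherent,
                 cutoff_keV = cutoff_keV),
            class = "xfi_transport")
}

#' @export
print.xfi_transport <- function(x, ...) {
  cat(sprintf(
    "<xfi_transport> %d primaries, %d events, transmitted %.3f, scale %.4g\n",
    x$n_primaries, nrow(x$events), x$transmitted_fraction, x$scale))
  invisible(x)
}

#' Weighted Compton-multiplicity histogram
#'
#' Sums detected-event weights by Compton-scatter multiplicity, restricted
#' to an energy window, in physical counts (event weights times the flux
#' scale factor).
#'
#' @param result An [run_position()] result.
#' @param window Length-2 energy interval in keV.
#' @param scatter_only Restrict to bulk-scatter-origin events (default
#'   `FALSE` tallies every event).
#' @return Named numeric vector: weighted counts per multiplicity.
#' @export
scatter_order_histogram <- function(result, window,
                                    scatter_only = FALSE) {
  ev <- result$events
  sel <- ev$energy_keV >= window[1] & ev$energy_keV <= window[2]
  if (scatter_only) sel <- sel & ev$origin == "scatter"
  ev <- ev[sel, , drop = FALSE]
  if (nrow(ev) == 0) return(numeric(0))
  out <- tapply(ev$weight * result$scale, ev$multiplicity, sum)
  v <- as.numeric(out)
  names(v) <- names(out)
  v
}

#' Modal Compton multiplicity in a window
#'
#' @param result An [run_position()] result.
#' @param window Energy window in keV.
#' @return The multiplicity holding the largest summed event weight.
#' @export
modal_multiplicity <- function(result, window) {
  h <- scatter_order_histogram(result, window)
  if (!length(h)) return(NA_integer_)
  as.integer(names(h)[which.max(h)])
}

#' Raster scan over a pixel grid
#'
#' Runs independent transport per pixel with per-pixel derived seeds and the
#' beam footprint re-centered on each pixel.
#'
#' @param phantom,beam,det As for [run_position()].
#' @param grid Data frame with columns `y` and `z` (pixel centers, mm), or a
#'   list with vectors `y`, `z` to be expanded into a full grid.
#' @param n_primaries Primaries per pixel.
#' @param seed Base seed; pixel i uses `(seed + 7919 * i) mod (2^31 - 1)`.
#' @param ... Passed on to [run_position()].
#' @return List of `xfi_transport` results, one per grid row, each carrying
#'   its `center_yz` and derived seed.
#' @export
run_scan <- function(phantom, beam, det, grid, n_primaries, seed = 1, ...) {
  if (!is.data.frame(grid)) grid <- expand.grid(y = grid$y, z = grid$z)
  if (nrow(grid) == 0) stop("empty scan grid", call. = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    run_position(phantom, beam, det, n_primaries,
                 seed = (seed + 7919 * i) %% (2^31 - 1),
                 center_yz = c(grid$y[i], grid$z[i]), ...)
  })
}
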
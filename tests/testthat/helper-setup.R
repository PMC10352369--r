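# shared acquisition defaults for the tests: the reference scan settings
ref_beam <- function(dwell_s = 0.75, ...) {
  beam_spec(53, 0, width_mm = 1, height_mm = 1, flux_per_s_mm2 = 8e10,
            dwell_s = dwell_s, ...)
}
ref_det <- function() detector_geometry(150, 57, 50)
ref_model <- function() detector_model()

water_phantom <- function(...) make_mouse_phantom(30, 60, ...)

# a manually constructed transport result with given events (for response
# bookkeeping tests without running the engine)
fake_transport <- function(energy, weight, mult = 0L, scale = 1,
                           dwell = 1) {
  structure(list(
    events = data.frame(energy_keV = energy, multiplicity = mult,
                        origin = factor("scatter"), weight = weight),
    n_primaries = length(energy), scale = scale,
    transmitted_fraction = 1,
    beam = beam_spec(dwell_s = dwell), det = ref_det(),
    center_yz = c(0, 0), seed = 0, forced = TRUE, coherent = FALSE,
    cutoff_keV = 15), class = "xfi_transport")
}

# synthetic spectrum: Gaussian peaks (area, center) over a flat background
# (counts per bin), Poisson-sampled unless noise = FALSE
synth_spectrum <- function(areas, centers, model, bg_per_bin = 50,
                           noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edges <- model$edges_keV
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mu <- rep(bg_per_bin, length(mids))
  for (i in seq_along(areas)) {
    s <- resolution_fwhm(model, centers[i]) / 2.3548200
    mu <- mu + areas[i] * diff(pnorm(edges, centers[i], s))
  }
  counts <- if (noise) rpois(length(mu), mu) else mu
  xfi_spectrum(edges, counts, livetime_s = 1)
}
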
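## File I/O: the plain-text spectrum dialect, YAML run configuration, and
## the synthetic fixture generator that makes the whole pipeline testable
## without external data.

#' Write a spectrum to the plain-text dialect
#'
#' Format: `# key: value` header lines (at least `livetime_s`,
#' `bin_width_keV`, `e_min_keV`), then `energy_keV,counts` rows with the
#' bin centers.
#'
#' @param spectrum An `xfi_spectrum` (uniform binning).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xfi_spectrum"))
  bw <- diff(spectrum$edges_keV)
  if (diff(range(bw)) > 1e-9 * mean(bw)) {
    stop("the spectrum dialect requires uniform bins", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# livetime_s: %.10g", spectrum$livetime_s), con)
  writeLines(sprintf("# bin_width_keV: %.10g", bw[1]), con)
  writeLines(sprintf("# e_min_keV: %.10g", spectrum$edges_keV[1]), con)
  for (k in names(spectrum$meta)) {
    v <- spectrum$meta[[k]]
    if (is.numeric(v)) v <- sprintf("%.10g", v)
    writeLines(sprintf("# %s: %s", k, v), con)
  }
  writeLines("energy_keV,counts", con)
  writeLines(sprintf("%.10g,%.10g", bin_centers(spectrum),
                     spectrum$counts), con)
  invisible(path)
}

#' Read a spectrum from the plain-text dialect
#'
#' Tolerates comment lines anywhere and both comma- and tab-delimited
#' rows.  A missing `livetime_s` header defaults to 1 s with a warning.
#'
#' @param path Input file path.
#' @return An `xfi_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- list()
  energy <- counts <- numeric(0)
  rowno <- 0
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
      if (length(m) == 3) {
        val <- m[3]
        num <- suppressWarnings(as.numeric(val))
        meta[[trimws(m[2])]] <- if (is.na(num)) val else num
      }
      next
    }
    parts <- strsplit(ln, "[,\t]")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("malformed spectrum row at line %d: '%s'", i, ln),
           call. = FALSE)
    }
    if (tolower(parts[1]) == "energy_kev") next  # column header
    v <- suppressWarnings(as.numeric(parts))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric spectrum row at line %d: '%s'", i, ln),
           call. = FALSE)
    }
    rowno <- rowno + 1
    energy[rowno] <- v[1]
    counts[rowno] <- v[2]
  }
  if (rowno < 2) stop("spectrum file contains fewer than 2 bins",
                      call. = FALSE)
  bw <- meta$bin_width_keV
  if (is.null(bw)) bw <- stats::median(diff(energy))
  livetime <- meta$livetime_s
  if (is.null(livetime)) {
    warning("no livetime_s header; defaulting to 1 s")
    livetime <- 1
  }
  meta$livetime_s <- NULL
  meta$bin_width_keV <- NULL
  meta$e_min_keV <- NULL
  edges <- c(energy - bw / 2, energy[rowno] + bw / 2)
  xfi_spectrum(edges, counts, livetime_s = livetime, meta = meta)
}

#' Read a run configuration
#'
#' Parses a YAML run configuration with `beam`, `phantom`, `detector`,
#' `analysis`, `reconstruction` and `simulation` blocks into package
#' objects, validating every referenced element and material.
#'
#' @param path YAML file path.
#' @return A list with components `beam` ([beam_spec()]), `phantom`
#'   ([make_mouse_phantom()] with deposits), `det_geometry`, `det_model`,
#'   `analysis`, `reconstruction`, `simulation`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' Validate a run-configuration list
#'
#' @param cfg A nested list as produced by [yaml::read_yaml()].
#' @return See [read_run_config()].
#' @export
as_run_config <- function(cfg) {
  gb <- function(block, key, default) {
    v <- cfg[[block]][[key]]
    if (is.null(v)) default else v
  }
  beam <- beam_spec(
    energy_keV = gb("beam", "energy_keV", 53),
    bandwidth_fwhm_keV = gb("beam", "bandwidth_fwhm_keV", 0),
    width_mm = gb("beam", "width_mm", 1),
    height_mm = gb("beam", "height_mm", 1),
    flux_per_s_mm2 = gb("beam", "flux_per_s_mm2", 8e10),
    dwell_s = gb("beam", "dwell_s", 1),
    polarization = gb("beam", "polarization", 0))
  mat_name <- gb("phantom", "material", "water")
  custom <- cfg$materials[[mat_name]]
  material <- if (!is.null(custom)) {
    xfi_material(mat_name, unlist(custom$fractions), custom$density_g_cm3)
  } else {
    builtin_material(mat_name)
  }
  phantom <- make_mouse_phantom(
    diameter_mm = gb("phantom", "diameter_mm", 30),
    length_mm = gb("phantom", "length_mm", 60),
    material = material)
  for (d in cfg$phantom$deposits) {
    dep <- marker_deposit(d$element, d$mass_ug, unlist(d$center),
                          shape = if (is.null(d$shape)) "sphere" else d$shape,
                          radius_mm = if (is.null(d$radius_mm)) 1 else d$radius_mm,
                          extents_mm = if (is.null(d$extents_mm)) c(1, 1, 1)
                                       else unlist(d$extents_mm))
    phantom <- add_deposit(phantom, dep)
  }
  det_geometry <- detector_geometry(
    angle_deg = gb("detector", "angle_deg", 150),
    distance_mm = gb("detector", "distance_mm", 57),
    area_mm2 = gb("detector", "area_mm2", 50))
  det_model <- detector_model(
    thickness_mm = gb("detector", "thickness_mm", 0.5),
    noise_fwhm_eV = gb("detector", "noise_fwhm_eV", 120),
    fano = gb("detector", "fano", 0.115),
    pair_eV = gb("detector", "pair_eV", 3.85))
  list(beam = beam, phantom = phantom, det_geometry = det_geometry,
       det_model = det_model,
       analysis = list(
         background = gb("analysis", "background", "linear"),
         z_threshold = gb("analysis", "z_threshold", 3)),
       reconstruction = list(
         n_depths = gb("reconstruction", "n_depths", 8)),
       simulation = list(
         n_primaries = gb("simulation", "n_primaries", 20000),
         seed = gb("simulation", "seed", 1),
         forced = gb("simulation", "forced", TRUE),
         coherent = gb("simulation", "coherent", FALSE)))
}

#' Fixture specification
#'
#' Describes a synthetic scan emulating the multi-site injection phantom:
#' marker deposits of graded masses at fixed sites inside a water-equivalent
#' body, raster-scanned on a regular pixel grid.  Deposit depths along the
#' beam axis are spread over the chord, which is the situation the
#' average-distribution attenuation correction is built for.
#'
#' `cells` and `mass_per_cell_pg` express a deposit budget in labelled-cell
#' terms: when given, the total deposited mass is `cells x mass_per_cell_pg
#' x 1e-6` ug distributed over the sites instead of the `mass_range`
#' geometric series.
#'
#' @param n_deposits Number of deposits (default 8 sites).
#' @param elements Element per deposit, recycled (default alternating
#'   iodine / palladium halves, as for a 50/50 labelled cell sample).
#' @param mass_range Range of deposit masses in ug; masses are geometrically
#'   spaced over the sites.
#' @param cells,mass_per_cell_pg Optional labelled-cell budget (see above).
#' @param pixel_mm Pixel size (square pixels).
#' @param grid_half_y,grid_half_z Half-extents of the pixel grid in mm.
#' @param n_primaries Primaries per pixel.
#' @param seed Base seed.
#' @param body_diameter_mm Body diameter.
#' @param deposit_radius_mm Deposit sphere radius.
#' @param foil_areal_ug_cm2 Areal density of the simulated calibration foil.
#' @return An object of class `xfi_fixture_spec`.
#' @export
fixture_spec <- function(n_deposits = 8,
                         elements = rep(c("I", "Pd"), each = 4),
                         mass_range = c(2, 20),
                         cells = NULL, mass_per_cell_pg = NULL,
                         pixel_mm = 1,
                         grid_half_y = 9, grid_half_z = 6,
                         n_primaries = 100000, seed = 1,
                         body_diameter_mm = 30,
                         deposit_radius_mm = 1.2,
                         foil_areal_ug_cm2 = 50) {
  elements <- rep_len(elements, n_deposits)
  masses <- if (!is.null(cells)) {
    stopifnot(!is.null(mass_per_cell_pg))
    total <- cells * mass_per_cell_pg * 1e-6  # pg -> ug
    rep(total / n_deposits, n_deposits)
  } else {
    exp(seq(log(mass_range[1]), log(mass_range[2]),
            length.out = n_deposits))
  }
  structure(list(n_deposits = n_deposits, elements = elements,
                 masses_ug = masses, pixel_mm = pixel_mm,
                 grid_half_y = grid_half_y, grid_half_z = grid_half_z,
                 n_primaries = n_primaries, seed = seed,
                 body_diameter_mm = body_diameter_mm,
                 deposit_radius_mm = deposit_radius_mm,
                 foil_areal_ug_cm2 = foil_areal_ug_cm2),
            class = "xfi_fixture_spec")
}

#' Phantom realizing a fixture specification
#'
#' Deposit sites sit on a fixed two-row arrangement in the scan plane.
#' Depths along the beam axis are placed at the chord fractions
#' `(i - 0.5) / n` of each site's own chord — the marker-depth family the
#' average-distribution attenuation correction assumes — visited in a
#' balanced low/high interleaved order so that the graded masses are not
#' monotonically confounded with depth.
#'
#' @param spec An [fixture_spec()].
#' @return An `xfi_phantom` with the specified deposits.
#' @export
fixture_phantom <- function(spec) {
  ph <- make_mouse_phantom(diameter_mm = spec$body_diameter_mm)
  n <- spec$n_deposits
  ys <- rep(c(-6, -2, 2, 6), length.out = n)
  zs <- rep(c(-3, 3), each = 4, length.out = n)
  # balanced order of chord fractions: mirrored pairs (k, n+1-k) assigned
  # outer/inner alternately, so that consecutive site blocks (and hence
  # each element of an alternating-element fixture) sample shallow and
  # deep depths evenly
  npair <- ceiling(n / 2)
  pair_ord <- as.vector(rbind(seq_len(ceiling(npair / 2)),
                              npair + 1 - seq_len(ceiling(npair / 2))))
  pair_ord <- unique(pair_ord[pair_ord <= npair])
  idx <- as.vector(rbind(pair_ord, n + 1 - pair_ord))[seq_len(n)]
  frac <- (idx - 0.5) / n
  R <- spec$body_diameter_mm / 2
  for (i in seq_len(n)) {
    half_chord <- sqrt(R^2 - ys[i]^2)
    x <- -half_chord + frac[i] * 2 * half_chord
    # keep the sphere inside the body: shrink toward the axis if needed
    lim <- sqrt(max((R - spec$deposit_radius_mm - 0.1)^2 - ys[i]^2, 0))
    x <- max(min(x, lim), -lim)
    ph <- add_deposit(ph, marker_deposit(
      spec$elements[i], spec$masses_ug[i], c(x, ys[i], zs[i]),
      radius_mm = spec$deposit_radius_mm))
  }
  ph
}

#' Simulate a reference-foil spectrum
#'
#' Transports the beam through a thin marker layer suspended in air and
#' applies the detector response, giving a calibration spectrum whose
#' ground-truth flux is the beam's.
#'
#' @param element Foil element.
#' @param areal_ug_cm2 Foil areal density in ug/cm^2.
#' @param beam,det,model Acquisition description.
#' @param n_primaries,seed Simulation budget.
#' @param noise Add Poisson counting noise.
#' @return An [foil_reference()] with the simulated spectrum.
#' @export
simulate_foil <- function(element, areal_ug_cm2, beam, det, model,
                          n_primaries = 50000, seed = 1, noise = TRUE) {
  side <- max(beam$width_mm, beam$height_mm) * 3
  thick <- 0.05
  mass <- areal_ug_cm2 / 100 * side^2          # ug over the foil area
  ph <- make_mouse_phantom(diameter_mm = 4 * side, length_mm = 4 * side,
                           material = builtin_material("air"))
  ph <- add_deposit(ph, marker_deposit(element, mass, c(0, 0, 0),
                                       shape = "box",
                                       extents_mm = c(thick, side, side)))
  tr <- run_position(ph, beam, det, n_primaries, seed = seed)
  sp <- apply_response(model, tr)
  if (noise) sp <- add_counting_noise(sp, seed = seed + 1)
  foil_reference(element, areal_ug_cm2, sp)
}

#' Generate an on-disk synthetic scan fixture
#'
#' Simulates the full scan described by a [fixture_spec()] and writes one
#' spectrum file per pixel, a calibration-foil spectrum, and a ground-truth
#' manifest (true deposit masses, per-pixel areal truth, all seeds) to a
#' directory.  Identical spec + seed produce identical files.
#'
#' @param spec An [fixture_spec()].
#' @param dir Output directory.
#' @param beam,det,model Acquisition description (defaults: the reference
#'   scan settings — 53 keV monochromatic, 1 x 1 mm footprint, 0.75 s
#'   dwell, 150 degree 57 mm 50 mm^2 detector, 0.5 mm silicon sensor).
#' @param overwrite Refuse to write into an existing directory unless TRUE.
#' @return The manifest, invisibly.
#' @export
generate_fixture <- function(spec, dir,
                             beam = beam_spec(dwell_s = 0.75),
                             det = detector_geometry(),
                             model = detector_model(),
                             overwrite = FALSE) {
  stopifnot(inherits(spec, "xfi_fixture_spec"))
  if (dir.exists(dir) && !overwrite) {
    stop("output directory exists; use overwrite = TRUE", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- fixture_phantom(spec)
  ys <- seq(-spec$grid_half_y, spec$grid_half_y, by = spec$pixel_mm)
  zs <- seq(-spec$grid_half_z, spec$grid_half_z, by = spec$pixel_mm)
  grid <- expand.grid(y = ys, z = zs)
  pix_truth <- list()
  for (i in seq_len(nrow(grid))) {
    yz <- c(grid$y[i], grid$z[i])
    pix_seed <- (spec$seed + 7919 * i) %% (2^31 - 1)
    tr <- run_position(ph, beam, det, spec$n_primaries, seed = pix_seed,
                       center_yz = yz)
    sp <- apply_response(model, tr)
    sp <- add_counting_noise(sp, seed = pix_seed + 1)
    sp$meta$pixel_index <- i
    write_spectrum(sp, file.path(dir, sprintf("pixel_%04d.csv", i)))
    truth <- lapply(unique(spec$elements), function(el) {
      areal_density_in_beam(ph, yz, spec$pixel_mm, spec$pixel_mm, el)
    })
    names(truth) <- unique(spec$elements)
    pix_truth[[i]] <- c(list(index = i, y = yz[1], z = yz[2],
                             seed = pix_seed), truth)
  }
  foil <- simulate_foil(spec$elements[1], spec$foil_areal_ug_cm2, beam,
                        det, model, n_primaries = 4 * spec$n_primaries,
                        seed = spec$seed + 999)
  write_spectrum(foil$spectrum, file.path(dir, "foil.csv"))
  manifest <- list(
    seed = spec$seed,
    n_primaries = spec$n_primaries,
    pixel_mm = spec$pixel_mm,
    grid_y = ys, grid_z = zs,
    body_diameter_mm = spec$body_diameter_mm,
    beam = list(energy_keV = beam$energy_keV,
                bandwidth_fwhm_keV = beam$bandwidth_fwhm_keV,
                width_mm = beam$width_mm, height_mm = beam$height_mm,
                flux_per_s_mm2 = beam$flux_per_s_mm2,
                dwell_s = beam$dwell_s),
    foil = list(element = spec$elements[1],
                areal_ug_cm2 = spec$foil_areal_ug_cm2,
                file = "foil.csv"),
    deposits = lapply(seq_len(spec$n_deposits), function(i) {
      d <- ph$deposits[[i]]
      list(element = d$element, mass_ug = d$mass_ug,
           center = as.list(d$center), radius_mm = d$radius_mm)
    }),
    pixels = pix_truth)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
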
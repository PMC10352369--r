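## Phantom geometry: a cylindrical bulk body (axis along z) carrying uniform
## marker deposits (spheres or axis-aligned boxes).  Coordinate convention:
## the pencil beam travels along +x, the scan raster lives in (y, z), and
## the fluorescence detector sits in the x-y plane.  Lengths in mm, masses
## in micrograms.

#' Marker deposit
#'
#' A localized uniform deposit of a fluorescence marker element inside the
#' phantom body.
#'
#' @param element Element symbol (`"I"`, `"Pd"`).
#' @param mass_ug Total marker mass in micrograms.
#' @param center Numeric length-3 center position `c(x, y, z)` in mm.
#' @param shape `"sphere"` or `"box"`.
#' @param radius_mm Sphere radius in mm (for `shape = "sphere"`).
#' @param extents_mm Length-3 box edge lengths in mm (for `shape = "box"`).
#' @return An object of class `xfi_deposit`.
#' @export
marker_deposit <- function(element, mass_ug, center,
                           shape = c("sphere", "box"),
                           radius_mm = 1, extents_mm = c(1, 1, 1)) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3, is.numeric(center))
  if (mass_ug <= 0) stop("deposit mass must be positive", call. = FALSE)
  el <- element_data(element)  # validates symbol
  if (is.null(el$lines)) {
    stop("element '", element, "' has no K-line data; cannot serve as marker",
         call. = FALSE)
  }
  vol <- if (shape == "sphere") {
    stopifnot(radius_mm > 0)
    4 / 3 * pi * radius_mm^3
  } else {
    stopifnot(all(extents_mm > 0))
    prod(extents_mm)
  }
  structure(list(element = element, mass_ug = mass_ug,
                 center = as.numeric(center), shape = shape,
                 radius_mm = radius_mm, extents_mm = as.numeric(extents_mm),
                 volume_mm3 = vol,
                 conc_ug_mm3 = mass_ug / vol),
            class = "xfi_deposit")
}

.deposit_bound_radius <- function(dep) {
  if (dep$shape == "sphere") dep$radius_mm else sqrt(sum((dep$extents_mm / 2)^2))
}

.deposit_inside_body <- function(dep, diameter, length) {
  r <- .deposit_bound_radius(dep)
  rad_xy <- sqrt(sum(dep$center[1:2]^2))
  (rad_xy + r) <= diameter / 2 + 1e-9 &&
    (abs(dep$center[3]) + r) <= length / 2 + 1e-9
}

.deposits_overlap <- function(a, b) {
  # conservative bounding-sphere test; deposits are required to be disjoint
  d <- sqrt(sum((a$center - b$center)^2))
  d < (.deposit_bound_radius(a) + .deposit_bound_radius(b))
}

#' Mouse-sized water-equivalent phantom
#'
#' Builds a cylindrical phantom (axis along z) of a bulk material,
#' defaulting to a 30 mm diameter water cylinder as a stand-in for a mouse
#' trunk.
#'
#' @param diameter_mm Body diameter in mm.
#' @param length_mm Body length in mm.
#' @param material Bulk [xfi_material]; default water.
#' @return An object of class `xfi_phantom` with an empty deposit list.
#' @examples
#' ph <- make_mouse_phantom()
#' ph <- add_deposit(ph, marker_deposit("I", 5, c(0, 0, 0)))
#' @export
make_mouse_phantom <- function(diameter_mm = 30, length_mm = 60,
                               material = builtin_material("water")) {
  if (diameter_mm <= 0 || length_mm <= 0) {
    stop("phantom dimensions must be positive", call. = FALSE)
  }
  stopifnot(inherits(material, "xfi_material"))
  structure(list(diameter_mm = diameter_mm, length_mm = length_mm,
                 material = material, deposits = list()),
            class = "xfi_phantom")
}

#' Add a marker deposit to a phantom
#'
#' Deposits must lie entirely inside the body and must not overlap existing
#' deposits (each deposit is the exclusive ground truth of its region).
#'
#' @param phantom An [make_mouse_phantom()] phantom.
#' @param deposit An [marker_deposit()].
#' @return The phantom with the deposit appended.
#' @export
add_deposit <- function(phantom, deposit) {
  stopifnot(inherits(phantom, "xfi_phantom"), inherits(deposit, "xfi_deposit"))
  if (!.deposit_inside_body(deposit, phantom$diameter_mm,
                            phantom$length_mm)) {
    stop("deposit does not fit inside the phantom body", call. = FALSE)
  }
  for (d in phantom$deposits) {
    if (.deposits_overlap(d, deposit)) {
      stop("deposit overlaps an existing deposit", call. = FALSE)
    }
  }
  phantom$deposits <- c(phantom$deposits, list(deposit))
  phantom
}

#' @export
print.xfi_phantom <- function(x, ...) {
  cat(sprintf("<xfi_phantom> %s cylinder, d = %g mm, L = %g mm, %d deposit(s)\n",
              x$material$name, x$diameter_mm, x$length_mm,
              length(x$deposits)))
  for (d in x$deposits) {
    cat(sprintf("  %-2s %8.3f ug at (%g, %g, %g) [%s]\n", d$element,
                d$mass_ug, d$center[1], d$center[2], d$center[3], d$shape))
  }
  invisible(x)
}

# ray/body intersection: returns c(t_enter, t_exit) or NULL.
# origin, dir in mm; dir need not be normalized here (it is by callers).
.ray_cylinder <- function(origin, dir, radius, half_len) {
  ox <- origin[1]; oy <- origin[2]; oz <- origin[3]
  dx <- dir[1]; dy <- dir[2]; dz <- dir[3]
  a <- dx^2 + dy^2
  t0 <- -Inf; t1 <- Inf
  if (a < 1e-14) {
    if (ox^2 + oy^2 > radius^2) return(NULL)
  } else {
    b <- 2 * (ox * dx + oy * dy)
    cc <- ox^2 + oy^2 - radius^2
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) return(NULL)
    sq <- sqrt(disc)
    t0 <- (-b - sq) / (2 * a)
    t1 <- (-b + sq) / (2 * a)
  }
  if (abs(dz) < 1e-14) {
    if (abs(oz) > half_len) return(NULL)
  } else {
    tz0 <- (-half_len - oz) / dz
    tz1 <- (half_len - oz) / dz
    lo <- min(tz0, tz1); hi <- max(tz0, tz1)
    t0 <- max(t0, lo); t1 <- min(t1, hi)
  }
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}

.ray_sphere <- function(origin, dir, center, radius) {
  oc <- origin - center
  b <- 2 * sum(oc * dir)
  cc <- sum(oc^2) - radius^2
  disc <- b^2 - 4 * cc
  if (disc <= 0) return(NULL)
  sq <- sqrt(disc)
  c((-b - sq) / 2, (-b + sq) / 2)
}

.ray_box <- function(origin, dir, center, extents) {
  t0 <- -Inf; t1 <- Inf
  for (i in 1:3) {
    h <- extents[i] / 2
    if (abs(dir[i]) < 1e-14) {
      if (abs(origin[i] - center[i]) > h) return(NULL)
    } else {
      ta <- (center[i] - h - origin[i]) / dir[i]
      tb <- (center[i] + h - origin[i]) / dir[i]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}

#' Transmission along a ray through the phantom
#'
#' Computes `exp(-sum mu * length)` along a ray, accounting for the bulk
#' body and the (dilute) marker content of any traversed deposits.
#'
#' @param phantom An `xfi_phantom`.
#' @param origin Ray origin `c(x, y, z)` in mm.
#' @param direction Ray direction (normalized internally).
#' @param E Photon energy in keV.
#' @param t_max Optional maximum path length (mm); default the full ray.
#' @param processes Attenuation processes to include: `"total"` (default) or
#'   a subset of the per-process coefficients summed together, e.g.
#'   `c("photoelectric", "incoherent")` for consistency with a transport run
#'   that excludes coherent scattering.
#' @return Transmission fraction in `[0, 1]`.
#' @examples
#' ph <- make_mouse_phantom()
#' path_attenuation(ph, c(-100, 0, 0), c(1, 0, 0), 28.6)
#' @export
path_attenuation <- function(phantom, origin, direction, E,
                             t_max = Inf, processes = "total") {
  stopifnot(inherits(phantom, "xfi_phantom"))
  direction <- direction / sqrt(sum(direction^2))
  mu_mat <- function(target, dens) {
    sum(vapply(processes, function(p) mu_over_rho(target, E, p),
               numeric(1))) * dens * 0.1  # per mm
  }
  mu_body <- mu_mat(phantom$material, phantom$material$density)
  body <- .ray_cylinder(origin, direction, phantom$diameter_mm / 2,
                        phantom$length_mm / 2)
  if (is.null(body)) return(1.0)
  t0 <- max(body[1], 0); t1 <- min(body[2], t_max)
  if (t1 <= t0) return(1.0)
  tau <- mu_body * (t1 - t0)
  for (d in phantom$deposits) {
    seg <- if (d$shape == "sphere") {
      .ray_sphere(origin, direction, d$center, d$radius_mm)
    } else {
      .ray_box(origin, direction, d$center, d$extents_mm)
    }
    if (is.null(seg)) next
    s0 <- max(seg[1], t0); s1 <- min(seg[2], t1)
    if (s1 <= s0) next
    mu_dep <- mu_mat(d$element, d$conc_ug_mm3 * 1e-3)  # ug/mm^3 -> g/cm^3
    tau <- tau + mu_dep * (s1 - s0)
  }
  exp(-tau)
}

# overlap volume of a deposit with the beam prism: all x, y and z within
# the footprint rectangle.  Boxes are analytic; spheres use fixed Gauss
# quadrature of the chord-length integral.
.deposit_beam_overlap_fraction <- function(dep, y_lo, y_hi, z_lo, z_hi) {
  if (dep$shape == "box") {
    oy <- max(0, min(y_hi, dep$center[2] + dep$extents_mm[2] / 2) -
                max(y_lo, dep$center[2] - dep$extents_mm[2] / 2))
    oz <- max(0, min(z_hi, dep$center[3] + dep$extents_mm[3] / 2) -
                max(z_lo, dep$center[3] - dep$extents_mm[3] / 2))
    return((oy / dep$extents_mm[2]) * (oz / dep$extents_mm[3]))
  }
  r <- dep$radius_mm
  ylo <- max(y_lo, dep$center[2] - r); yhi <- min(y_hi, dep$center[2] + r)
  zlo <- max(z_lo, dep$center[3] - r); zhi <- min(z_hi, dep$center[3] + r)
  if (ylo >= yhi || zlo >= zhi) return(0)
  n <- 48
  gy <- ylo + (yhi - ylo) * (seq_len(n) - 0.5) / n
  gz <- zlo + (zhi - zlo) * (seq_len(n) - 0.5) / n
  dy <- (yhi - ylo) / n; dz <- (zhi - zlo) / n
  yy <- outer(gy - dep$center[2], rep(1, n))
  zz <- outer(rep(1, n), gz - dep$center[3])
  chord <- 2 * sqrt(pmax(0, r^2 - yy^2 - zz^2))
  sum(chord) * dy * dz / dep$volume_mm3
}

#' Marker areal density within a beam footprint
#'
#' Marker mass intersecting the beam prism (footprint rectangle in (y, z),
#' extruded along the beam axis x) divided by the footprint area.
#'
#' @param phantom An `xfi_phantom`.
#' @param center_yz Footprint center `c(y, z)` in mm.
#' @param width_mm,height_mm Footprint width (y) and height (z) in mm.
#' @param element Element symbol to tally.
#' @return Areal density in ug/mm^2.
#' @export
areal_density_in_beam <- function(phantom, center_yz, width_mm, height_mm,
                                  element) {
  stopifnot(inherits(phantom, "xfi_phantom"))
  y_lo <- center_yz[1] - width_mm / 2; y_hi <- center_yz[1] + width_mm / 2
  z_lo <- center_yz[2] - height_mm / 2; z_hi <- center_yz[2] + height_mm / 2
  mass <- 0
  for (d in phantom$deposits) {
    if (d$element != element) next
    mass <- mass + d$mass_ug *
      .deposit_beam_overlap_fraction(d, y_lo, y_hi, z_lo, z_hi)
  }
  mass / (width_mm * height_mm)
}

#' Voxelize the marker deposits
#'
#' Rasterizes deposit concentrations onto a regular grid (2x2x2 subsampling
#' per voxel), mainly for inspection and mass-conservation checks.
#'
#' @param phantom An `xfi_phantom`.
#' @param voxel_mm Voxel edge length in mm.
#' @param element Element to rasterize.
#' @return A data frame of occupied voxels with columns `x`, `y`, `z`
#'   (centers, mm) and `mass_ug`.
#' @export
voxelize_deposits <- function(phantom, voxel_mm = 0.1, element) {
  out <- list()
  for (d in phantom$deposits) {
    if (d$element != element) next
    r <- .deposit_bound_radius(d)
    lo <- floor((d$center - r) / voxel_mm) * voxel_mm
    hi <- ceiling((d$center + r) / voxel_mm) * voxel_mm
    gx <- seq(lo[1] + voxel_mm / 2, hi[1], by = voxel_mm)
    gy <- seq(lo[2] + voxel_mm / 2, hi[2], by = voxel_mm)
    gz <- seq(lo[3] + voxel_mm / 2, hi[3], by = voxel_mm)
    g <- expand.grid(x = gx, y = gy, z = gz)
    sub <- expand.grid(sx = c(-0.25, 0.25), sy = c(-0.25, 0.25),
                       sz = c(-0.25, 0.25)) * voxel_mm
    frac <- rep(0, nrow(g))
    for (i in seq_len(nrow(sub))) {
      px <- g$x + sub$sx[i]; py <- g$y + sub$sy[i]; pz <- g$z + sub$sz[i]
      inside <- if (d$shape == "sphere") {
        (px - d$center[1])^2 + (py - d$center[2])^2 +
          (pz - d$center[3])^2 <= d$radius_mm^2
      } else {
        abs(px - d$center[1]) <= d$extents_mm[1] / 2 &
          abs(py - d$center[2]) <= d$extents_mm[2] / 2 &
          abs(pz - d$center[3]) <= d$extents_mm[3] / 2
      }
      frac <- frac + inside / nrow(sub)
    }
    keep <- frac > 0
    vox_mass <- frac[keep] * voxel_mm^3 * d$conc_ug_mm3
    out[[length(out) + 1]] <- data.frame(x = g$x[keep], y = g$y[keep],
                                         z = g$z[keep], mass_ug = vox_mass)
  }
  if (!length(out)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      mass_ug = numeric(0)))
  }
  do.call(rbind, out)
}
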
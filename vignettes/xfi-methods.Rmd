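---
title: "Models and methods behind xfiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xfiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Scanning-beam X-ray fluorescence imaging (XFI) maps marker elements
(typically iodine or palladium, used to label cells or as molecular
tracers) inside small animals by raster-scanning a monochromatic pencil
beam and spectroscopically detecting the markers' characteristic K
fluorescence. The detection sensitivity is governed by the significance

$$Z = \frac{S}{\sqrt{B}},$$

where $S$ is the number of fluorescence photons fitted in a window of
about three detector FWHM around the line, and $B$ the spectral background
under it. In a mouse-sized water-equivalent body probed at 53 keV, that
background in the iodine K$\alpha$ region (around 28.6 keV) is not made of
singly scattered photons — a single 150-degree Compton scatter of a 53 keV
photon still leaves 44.4 keV. Kinematically at least five successive
scatters are needed to reach 28.6 keV, so the background is a
multiple-Compton continuum, and quantifying it requires Monte-Carlo photon
transport. `xfiquant` implements that simulator and the full
quantification chain (peak fitting, flux calibration, attenuation-corrected
mass reconstruction, dose bookkeeping) in one package.

# Physics data and scattering model

Cross sections are shipped as plain-text tables (`inst/extdata/attenuation`)
on a ~200-point log grid over 1–100 keV with explicit K-edge rows,
compiled from the standard NIST/XCOM-style values; lookups use log–log
interpolation. Composite checks (water total $\mu/\rho \approx 0.376$
cm$^2$/g at 30 keV, water $\mu_{en}/\rho$, silicon photoelectric working
points) are asserted in the test suite.

Compton scattering uses the free-electron Klein–Nishina model throughout —
closed-form differential and total cross sections, rejection sampling of
the polar angle, and exact energy–angle consistency
$E' = E/(1 + (E/m_ec^2)(1-\cos\theta))$. Doppler broadening and the
incoherent scattering function are omitted; above ~15 keV in low-Z tissue
this is a few-percent-level approximation, and it slightly overestimates
small-angle incoherent scattering. An optional linear-polarization flag
adds the standard azimuthal modulation for the first scatter (synchrotron
beams are horizontally polarized); the default is unpolarized.

Coherent (Rayleigh) scattering cannot move energy into the signal window
from a monochromatic beam, so it is excluded from transport by default
(an optional flag includes it with a Thomson angular shape). To keep the
simulator and the reconstruction consistent, the attenuation corrections
default to the same process set (photoelectric + incoherent); the
standalone `path_attenuation()` defaults to the total coefficient.

# Monte-Carlo transport

`run_position()` transports primaries sampled from the beam band (Gaussian
FWHM; 0 = monochromatic) along $+x$ through a cylindrical body (axis
along $z$) carrying spherical or box deposits. The walk is analog:
exponential free paths from the local linear attenuation, process choice
proportional to the partial cross sections, termination on photoelectric
absorption, escape, or the 15 keV cutoff (photons cannot up-scatter, and
every window of interest lies above 15 keV).

Two variance-reduction estimators produce the detected events:

* **Compton background** — at every incoherent vertex a weighted event is
  scored toward the detector, treated as a point at 57 mm with solid angle
  $A/d^2$ evaluated per vertex: weight = (directional Klein–Nishina
  probability) × (solid angle) × (escape transmission at the scattered
  energy). The photon then continues analog.
* **Fluorescence** — a track-length (expected-value) estimator integrates
  K-line production, $\mu_{K} = \tau(E)\,(1-1/J_K)\,\omega_K f_\ell$,
  along every flown path segment inside a deposit and scores the direct
  detection of each line (isotropic emission: $\Delta\Omega/4\pi$ times
  escape transmission, geometry evaluated at the segment midpoint).
  Sampled photoelectric vertices on the marker still spawn an analog
  fluorescence photon whose *scattered* detections are scored by the
  Compton estimator; its direct detection is not scored again, so the two
  channels do not double count.

With forced detection off, the run is fully analog and an event is scored
when an escaping photon crosses the detector aperture disc; the test suite
verifies that the two modes agree on a thin slab where analog statistics
are feasible.

Event records carry the photon's Compton multiplicity and origin
(`scatter` or `fluorescence:element:line`), which is how the
multiplicity decomposition of the background (`scatter_order_histogram()`)
is obtained. Scans derive per-pixel seeds as
`(seed + 7919 * pixel_index) mod (2^31 - 1)` and re-center beam and
detector per pixel (in the experiment the object is translated while beam
and detector stay fixed). Continuous-scan motion is approximated by a
static per-pixel dwell; blur within the ~1 mm travel is out of scope.

# Detector response

The silicon drift detector is modelled by two ingredients:

* **Full-energy-peak efficiency** = the probability of *photoelectric*
  absorption in the sensor, $1-\exp(-\tau/\rho\cdot\rho t)$. This is the
  interpretation consistent with both printed working points of a 0.5 mm
  sensor — about 4% at 44 keV (where the single-scatter Compton bump
  lands) and about 14% in the iodine K$\alpha$ region; counting all
  interactions would give roughly 6.5% at 44 keV. Compton interactions in
  a thin sensor deposit only partial energy and do not contribute to the
  photopeak.
* **Resolution** $\mathrm{FWHM}(E) = 2.355\sqrt{F\,\varepsilon E +
  \sigma_{noise}^2}$ with defaults Fano $F = 0.115$, pair-creation energy
  $\varepsilon = 3.85$ eV and 120 eV electronic noise FWHM — representative
  fast-SDD values, exposed in the configuration since no measured figure
  is available for the reference device. At 28.6 keV this gives about
  0.29 keV FWHM, which leaves the iodine K$\alpha_1$/K$\alpha_2$ doublet
  (295 eV apart) unresolved.

`apply_response()` deterministically spreads each event's
weight × efficiency over the 0.05 keV bins as a Gaussian and scales to
physical counts (flux × footprint × dwell / primaries);
`add_counting_noise()` Poisson-samples the expected spectrum. Escape
peaks, tailing, pile-up and charge sharing are not modelled.

# Peak fitting and significance

`fit_peaks()` performs a weighted least-squares fit over each line
cluster's window (centroid ± 3 FWHM, merged when windows overlap):
Gaussians with centers fixed at the tabulated line energies and widths
fixed by the resolution model, the K$\alpha$ doublet tied to its tabulated
intensity ratio with a single free amplitude, on a local linear background
(quadratic optional). Weights are Poisson, taken from the *fitted* model
via two IRLS refinements — weighting by the observed counts systematically
underweights upward fluctuations and biases amplitudes low on noisy
spectra. $S$ is the fitted area (clamped at zero for reporting; the
unconstrained `S_raw` is kept for null checks), $B$ the fitted-background
integral over the 3-FWHM window, and $Z = S/\sqrt{B}$ from the fitted
quantities. A fit with $B = 0$ and $S > 0$ is reported as degenerate
rather than infinitely significant.

`bandwidth_study()` re-runs transport + response + fit over a grid of beam
bandwidths and deposit masses at a fixed photon budget. It reproduces the
design argument for near-monochromatic sources: $Z$ is flat up to ~5 keV
FWHM and collapses toward 15 keV because band-tail photons need only one
or two scatters to reach the signal window, inflating $B$ — the effect is
strongest at low marker concentration.

# From counts to mass

The thin-target forward model for the fitted K$\alpha$ counts of a pixel
with marker areal density $\rho_A$ (µg/mm²) is

$$S = N_{ph}\,\rho_A \sum_\ell \sigma_\ell(E_0)\; T_{in}\,
\frac{\Delta\Omega}{4\pi}\, T_{out}\,\varepsilon(E_\ell),$$

with $N_{ph}$ = flux × footprint × dwell and $\sigma_\ell$ the K-line mass
production cross section. Three corrections make the inversion
quantitative:

* **Flux calibration.** Reference foils of known areal density, measured
  (here: simulated) in air, are fitted and the model inverted with
  $T_{in} = T_{out} = 1$; multiple foils combine by inverse-variance
  weighting, with a 5σ pairwise consistency guard. Because the calibration
  runs through the same simulator and fit, systematic normalization
  factors cancel in the end-to-end mass scale.
* **Average-distribution attenuation correction.** The marker depth along
  a pixel's beam chord is unknown in a 2D scan. The correction assumes 8
  point depths equally spaced along the chord and averages, per depth, the
  product of beam transmission to the depth, fluorescence transmission
  from it toward the detector, and the solid-angle ratio
  $(d_{ref}/d)^2$. The geometric factor matters: at 150 degrees the
  detector sits on the upstream side, so a marker at the entry of a 30 mm
  chord subtends ~1.5× the reference solid angle and one at the exit
  ~0.7×. The family of 8 depths is a configuration choice
  (`n_depths`); any smooth along-chord family is admissible. For a marker
  at a single unknown depth the correction can be off by several tens of
  percent (strongly so for the softer Pd K$\alpha$); it is unbiased when
  marker depth is effectively uniform along the chord, which is the
  distributed-marker situation it is designed for.
* **Secondary-excitation (enhancement) correction.** Photons scattered
  out of the beam can still exceed the marker K edge and excite deposits
  far from the current pixel. This genuine fluorescence halo survives any
  $Z$ threshold and, left uncorrected, inflates a summed multi-deposit
  map by tens of percent. `build_maps()` therefore subtracts a
  first-order model of it: `secondary_excitation_kernel()` integrates single-scatter
  vertices along each pixel's chord against depth-averaged source
  positions, giving expected halo counts per µg of source mass, and the
  inversion iterates to self-consistency. The scattered photon's transport
  to the source carries a linear buildup factor $(1+\mu d)e^{-\mu d}$ as a
  standard stand-in for the multiply-scattered fluence beyond first
  order; the residual after correction is at the few-percent level.

Pixels with $Z$ below the threshold (default 3; 3–5 is the conventional
false-positive guard) are zeroed in the map but keep their values and
uncertainties in the pixel table. Totals are reported in µg.

# Dose

`local_dose()` computes the kerma of one scan position: fluence × photon
energy × $\mu_{en}/\rho$, attenuated to depth, with no electron transport
(the kerma approximation is standard at these energies). In the
continuous-scan mode the spectra of one position are recorded over a 1 mm
travel of the 0.1 × 1.0 mm beam, so the photons spread over
(travel + width) × height; with the reference settings (8×10¹⁰ /s/mm²,
0.75 s) this yields ≈176 mGy at the surface, consistent with the published
per-position figures and comfortably below the 300 mGy level at which
irradiated T cells still self-repair. `travel_mm = 0` recovers the static
footprint normalization (≈10× higher).

# The synthetic-data generator

`fixture_spec()`/`generate_fixture()` emulate a multi-site injection scan:
eight spherical deposits (radius 1.2 mm) in a 30 mm water cylinder on a
two-row site pattern, raster-scanned at 1 mm pitch with the reference
beam and detector, plus a simulated calibration foil and a ground-truth
manifest. Two mass modes exist: a geometric series over a mass range
(default 2–20 µg, emulating site-to-site concentration variation) and a
labelled-cell budget (`cells` × `mass_per_cell_pg`, e.g. 10⁷ cells at
31.1 pg/cell = 311 µg total split equally). Deposit depths sit at the
chord fractions $(i-0.5)/8$ of each site's own chord, visited in a
balanced outer/inner order so neither the mass grading nor an element
split is confounded with depth — this matches the uniform-depth assumption
of the attenuation correction, which is the regime the method is designed
for (and the regime in which the published whole-map recovery is claimed).

What the generator does *not* emulate: anatomy and heterogeneous organs
(single bulk material), bone or lung, motion blur, detector pile-up or
escape peaks, beam-intensity drifts. Passing the round-trip tests
therefore demonstrates the self-consistency and statistical correctness of
the chain under the stated physics, not robustness to those effects.

A practical caveat for interpreting simulated scans: with $n$ primaries a
forced-detection event represents flux × footprint × dwell / $n$ physical
photons, so at small $n$ the background acquires spiky granularity that
Poisson statistics do not describe; fitted uncertainties then refer only
to the counting noise. The shipped defaults (10⁵ per pixel for fixtures,
10⁶ for single-position studies) keep this simulation noise below the
counting noise at the reference flux. Problem sizes used by the test
suite follow the same choices scaled to a few minutes of runtime.

# Known limitations

* Free-electron Compton model (no Doppler broadening / S(q,Z)); slightly
  hard small-angle scattering, a few-percent effect on the halo kernel.
* The secondary-excitation correction is first order plus a linear
  buildup approximation.
* The average-distribution correction is a projection-imaging
  approximation; single localized deposits at unknown depth carry a
  systematic of tens of percent that only 3D imaging resolves.
* No L-shell physics, electron transport, bremsstrahlung or escape peaks.
* The detector is a point in the forced-detection estimator (aperture
  57 mm away, ≪ valid for the 8 mm aperture radius).
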
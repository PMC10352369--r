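test_that("significance arithmetic and guards", {
  expect_equal(significance(100, 400), 5)
  expect_equal(significance(0, 400), 0)
  # the conventional minimum detectability threshold
  expect_equal(significance(30, 100), 3)
  expect_error(significance(10, 0), "degenerate")
  expect_error(significance(-1, 10), "non-negative")
})

test_that("signal window is three detector FWHM by default", {
  m <- ref_model()
  w <- signal_window(28.6, m)
  expect_equal(diff(w), 3 * resolution_fwhm(m, 28.6), tolerance = 1e-12)
  expect_equal(mean(w), 28.6)
})

test_that("peak fit recovers a known Gaussian area on flat background", {
  m <- ref_model()
  lines <- emission_lines("I")
  ka <- lines[lines$line %in% c("Ka1", "Ka2"), ]
  area <- 10000
  sp <- synth_spectrum(area * ka$rel_intensity / sum(ka$rel_intensity),
                       ka$energy_keV, m, bg_per_bin = 40, seed = 101)
  ft <- fit_peaks(sp, "I", m)
  row <- ft[ft$group == "Ka", ]
  expect_true(row$converged)
  expect_lt(abs(row$S - area), 3 * row$S_se)
  expect_gt(row$Z, 5)
  # B close to the generated background integral over the 3 FWHM window
  win <- signal_window(sum(ka$energy_keV * ka$rel_intensity) /
                         sum(ka$rel_intensity), m)
  expect_equal(row$B, 40 * diff(win) / 0.05, tolerance = 0.15)
})

test_that("null spectra give S consistent with zero and few false positives", {
  m <- ref_model()
  set.seed(202)
  n_trial <- 300
  z_hits <- 0
  s_raw <- s_se <- numeric(n_trial)
  for (i in seq_len(n_trial)) {
    sp <- synth_spectrum(numeric(0), numeric(0), m, bg_per_bin = 60)
    ft <- fit_peaks(sp, "I", m)
    row <- ft[ft$group == "Ka", ]
    s_raw[i] <- row$S_raw
    s_se[i] <- row$S_se
    if (row$Z > 3) z_hits <- z_hits + 1
  }
  # unconstrained estimates consistent with zero truth
  expect_lt(mean(abs(s_raw) < 3 * s_se), 1.01)
  expect_gt(mean(abs(s_raw) < 3 * s_se), 0.98)
  # false-positive rate at Z > 3 below 1% (Gaussian tail ~0.13% per trial)
  expect_lt(z_hits / n_trial, 0.01)
})

test_that("fitted area is stable under widening the fit region", {
  m <- ref_model()
  lines <- emission_lines("I")
  ka <- lines[lines$line %in% c("Ka1", "Ka2"), ]
  sp <- synth_spectrum(8000 * ka$rel_intensity / sum(ka$rel_intensity),
                       ka$energy_keV, m, bg_per_bin = 30, seed = 77)
  s3 <- fit_peaks(sp, "I", m, region_fwhm = 3)
  s4 <- fit_peaks(sp, "I", m, region_fwhm = 4)
  expect_equal(s4$S[s4$group == "Ka"] / s3$S[s3$group == "Ka"], 1,
               tolerance = 0.02)
})

test_that("fitted S is unbiased across the S/B range", {
  m <- ref_model()
  lines <- emission_lines("I")
  ka <- lines[lines$line %in% c("Ka1", "Ka2"), ]
  frac <- ka$rel_intensity / sum(ka$rel_intensity)
  set.seed(303)
  n_rep <- 200
  pull <- numeric(n_rep)
  sb <- exp(seq(log(0.1), log(10), length.out = n_rep))
  for (i in seq_len(n_rep)) {
    bg <- 50
    win_bins <- 3 * resolution_fwhm(m, 28.5) / 0.05
    area <- sb[i] * bg * win_bins
    sp <- synth_spectrum(area * frac, ka$energy_keV, m, bg_per_bin = bg)
    ft <- fit_peaks(sp, "I", m)
    row <- ft[ft$group == "Ka", ]
    pull[i] <- (row$S_raw - area) / row$S_se
  }
  # mean pull consistent with zero at 2 sigma of the mean
  expect_lt(abs(mean(pull)), 2 / sqrt(n_rep) * sd(pull) + 0.05)
  expect_lt(sd(pull), 1.5)
})

test_that("quadratic background option fits curved continua", {
  m <- ref_model()
  edges <- m$edges_keV
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mu <- 100 + 2 * (mids - 28)^2
  set.seed(9)
  sp <- xfi_spectrum(edges, rpois(length(mu), mu))
  ft <- fit_peaks(sp, "I", m, background = "quadratic")
  row <- ft[ft$group == "Ka", ]
  expect_lt(abs(row$S_raw), 4 * row$S_se)
})

test_that("significance scales with the square root of dwell time", {
  ph <- add_deposit(water_phantom(),
                    marker_deposit("I", 2, c(0, 0, 0), radius_mm = 1))
  det <- ref_det(); m <- ref_model()
  z_of <- function(dwell) {
    tr <- run_position(ph, ref_beam(dwell_s = dwell), det, 4e4, seed = 50)
    ft <- fit_peaks(apply_response(m, tr), "I", m)
    ft$Z[ft$group == "Ka"]
  }
  # identical event sets scaled by dwell: S and B both linear in t
  expect_equal(z_of(1.5) / z_of(0.75), sqrt(2), tolerance = 0.02)
})

test_that("bandwidth study reproduces the design-curve shape", {
  ph <- add_deposit(water_phantom(),
                    marker_deposit("I", 0.5, c(0, 0, 0), radius_mm = 1))
  tab <- bandwidth_study(ph, ref_beam(), c(0, 5, 15), 0.5, ref_det(),
                         ref_model(), n_primaries = 1e6, seed = 60)
  z0 <- tab$Z[tab$bandwidth_fwhm_keV == 0]
  z5 <- tab$Z[tab$bandwidth_fwhm_keV == 5]
  z15 <- tab$Z[tab$bandwidth_fwhm_keV == 15]
  # flat up to 5 keV, then a drastic reduction for a low concentration
  expect_lt(abs(z5 - z0) / z0, 0.25)
  expect_lt(z15, 0.8 * z0)
})
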
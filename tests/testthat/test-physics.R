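test_that("Compton kinematics reproduce the closed form", {
  # 53 keV backscattered through the detector angle lands at ~44.4 keV
  expect_equal(compton_energy(53, 150 * pi / 180), 44.406, tolerance = 1e-4)
  expect_equal(compton_energy(53, 0), 53)
  # 180 degrees: hand evaluation 53 / (1 + 2 * 53 / 511)
  expect_equal(compton_energy(53, pi), 53 / (1 + 2 * 53 / 511),
               tolerance = 1e-12)
  expect_error(compton_energy(-1, 0), "positive")
  expect_error(compton_energy(53, 4), "0, pi")
})

test_that("Compton energy is monotone non-increasing in angle", {
  th <- seq(0, pi, length.out = 200)
  E <- compton_energy(53, th)
  expect_true(all(diff(E) <= 1e-12))
  expect_true(all(E >= compton_energy(53, pi) - 1e-12))
})

test_that("Klein-Nishina differential cross section has the right limits", {
  # forward scattering is the energy-independent Thomson value r_e^2
  expect_equal(klein_nishina_dcs(53, 0), 7.940787e-26, tolerance = 1e-6)
  expect_equal(klein_nishina_dcs(500, 0), 7.940787e-26, tolerance = 1e-6)
  expect_lt(klein_nishina_dcs(53, pi / 2), klein_nishina_dcs(53, 0))
  expect_true(all(klein_nishina_dcs(53, seq(0, pi, 0.1)) > 0))
})

test_that("numerical solid-angle integral matches the closed-form total", {
  th <- seq(0, pi, length.out = 20001)
  dcs <- klein_nishina_dcs(53, th)
  num <- 2 * pi * sum(dcs * sin(th)) * (th[2] - th[1])
  expect_equal(num, kn_total_xs(53), tolerance = 1e-3)
})

test_that("sampled Compton angles follow the Klein-Nishina density", {
  set.seed(42)
  n <- 2e5
  th <- sample_compton_angle(53, n)
  # chi-square against the normalized analytic density
  breaks <- seq(0, pi, length.out = 41)
  obs <- table(cut(th, breaks))
  grid <- seq(0, pi, length.out = 4001)
  dens <- klein_nishina_dcs(53, grid) * sin(grid)
  cdf <- cumsum(dens) / sum(dens)
  p_bin <- diff(approx(grid, cdf, breaks, rule = 2)$y)
  chi2 <- sum((as.numeric(obs) - n * p_bin)^2 / (n * p_bin))
  expect_gt(pchisq(chi2, df = 39, lower.tail = FALSE), 0.01)
  # empirical CDF close to analytic (KS distance)
  ks <- max(abs(ecdf(th)(grid) - cdf))
  expect_lt(ks, 0.005)
})

test_that("sampler is deterministic under seeding", {
  set.seed(7)
  a <- sample_compton_angle(53, 100)
  set.seed(7)
  b <- sample_compton_angle(53, 100)
  expect_identical(a, b)
})

test_that("low-energy limit approaches the Thomson angular shape", {
  set.seed(3)
  th <- sample_compton_angle(1, 2e5)
  # Thomson: density ~ (1 + cos^2) sin(theta); symmetric about pi/2 in cos
  ct <- cos(th)
  expect_lt(abs(mean(ct)), 0.01)
  grid <- seq(0, pi, length.out = 2001)
  dens <- (1 + cos(grid)^2) * sin(grid)
  cdf <- cumsum(dens) / sum(dens)
  ks <- max(abs(ecdf(th)(grid) - cdf))
  expect_lt(ks, 0.01)
})

test_that("mass attenuation lookup matches published water values", {
  water <- builtin_material("water")
  # standard tabulated value ~0.3756 cm^2/g at 30 keV
  expect_equal(mu_over_rho(water, 30, "total"), 0.3756, tolerance = 0.02)
  expect_equal(mu_over_rho(water, 50, "total"), 0.2269, tolerance = 0.02)
  expect_equal(mu_over_rho(water, 30, "energy_absorption"), 0.1557,
               tolerance = 0.03)
})

test_that("total coefficient bounds the components and decreases 10-60 keV", {
  for (target in list("Si", builtin_material("water"), "I")) {
    E <- c(15, 20, 30, 40, 55)
    tot <- mu_over_rho(target, E, "total")
    for (p in c("photoelectric", "incoherent", "coherent")) {
      expect_true(all(tot >= mu_over_rho(target, E, p) - 1e-12))
    }
  }
  E <- seq(10, 60, by = 1)
  expect_true(all(diff(mu_over_rho("Si", E, "total")) < 0))
  expect_error(mu_over_rho("Si", 500, "total"), "grid")
})

test_that("fluorescence production follows yield, jump and line ratios", {
  s1 <- fluorescence_production_xs("I", "Ka1", 53)
  s2 <- fluorescence_production_xs("I", "Ka2", 53)
  expect_gt(s1, 0)
  lines <- emission_lines("I")
  r <- lines$rel_intensity[lines$line == "Ka1"] /
    lines$rel_intensity[lines$line == "Ka2"]
  expect_equal(s1 / s2, r, tolerance = 1e-9)
  expect_gt(fluorescence_production_xs("Pd", "Ka1", 53), 0)
  # below the K edge excitation is impossible and must be signalled
  expect_error(fluorescence_production_xs("I", "Ka1", 33.0), "below")
  # continuity above the edge: approaching from above stays finite/positive
  eps <- fluorescence_production_xs("I", "Ka1", 33.18)
  expect_gt(eps, 0)
})

test_that("emission line intensities are normalized and below the edge", {
  for (el_sym in c("I", "Pd")) {
    el <- element_data(el_sym)
    expect_equal(sum(el$lines$rel_intensity), 1, tolerance = 1e-6)
    expect_true(all(el$lines$energy_keV < el$k_edge_keV))
    expect_true(el$omega_k > 0 && el$omega_k < 1)
    expect_gt(el$k_jump, 1)
  }
})

test_that("minimum scatter count is the iterated 180-degree loss", {
  # kinematic floor of the multiple-Compton background under the iodine line
  expect_identical(min_compton_scatters(53, 28.61), 5L)
  expect_identical(min_compton_scatters(53, 53), 0L)
  expect_identical(min_compton_scatters(53, 44.0), 1L)
  expect_error(min_compton_scatters(53, 54), "exceed")
})

test_that("materials validate their invariants", {
  expect_error(xfi_material("x", c(H = 0.5, O = 0.4), 1), "sum to 1")
  expect_error(xfi_material("x", c(H = 1), -1), "positive")
  expect_error(xfi_material("x", c(Xx = 1), 1), "no data")
  w <- builtin_material("water")
  expect_equal(sum(w$fractions), 1, tolerance = 1e-12)
})
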
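test_that("a plain water phantom produces only scattered events", {
  tr <- run_position(water_phantom(), ref_beam(), ref_det(),
                     n_primaries = 5000, seed = 1)
  expect_true(all(tr$events$origin == "scatter"))
  # the unscattered beam cannot reach a 150-degree detector
  expect_true(all(tr$events$multiplicity >= 1))
  expect_true(all(tr$events$energy_keV <= 53 + 1e-9))
  expect_gt(tr$transmitted_fraction, 0.4)
  expect_lt(tr$transmitted_fraction, 0.7)
})

test_that("single-scatter events cluster at the 150-degree Compton line", {
  tr <- run_position(water_phantom(), ref_beam(), ref_det(),
                     n_primaries = 5e4, seed = 2)
  ev <- tr$events
  single <- ev[ev$multiplicity == 1, ]
  # weighted mean energy of single-scatter events near compton_energy(53,150deg)
  m <- sum(single$energy_keV * single$weight) / sum(single$weight)
  expect_equal(m, compton_energy(53, 150 * pi / 180), tolerance = 0.02)
  expect_identical(modal_multiplicity(tr, c(43, 46)), 1L)
})

test_that("deep signal-window background is dominated by multiplicity >= 5", {
  tr <- run_position(water_phantom(), ref_beam(), ref_det(),
                     n_primaries = 3e5, seed = 3)
  expect_gte(modal_multiplicity(tr, c(26, 31)), 5L)
  # no event in the window below the kinematic floor minus one
  h <- scatter_order_histogram(tr, c(26, 31))
  expect_true(all(as.integer(names(h)) >= 4))
  # empty window
  expect_length(scatter_order_histogram(tr, c(5, 10)), 0)
})

test_that("iodine deposits emit their K lines with zero scatter count", {
  ph <- add_deposit(water_phantom(),
                    marker_deposit("I", 10, c(0, 0, 0), radius_mm = 1.5))
  tr <- run_position(ph, ref_beam(), ref_det(), n_primaries = 2e4,
                     seed = 4)
  fl <- tr$events[tr$events$multiplicity == 0, ]
  expect_gt(nrow(fl), 0)
  expect_true(all(grepl("^fluorescence:I:", fl$origin)))
  expect_setequal(unique(fl$energy_keV), c(28.612, 28.317, 32.295))
  # line weights follow the tabulated intensity ratio (equal escape paths)
  w <- tapply(fl$weight, droplevels(fl$origin), sum)
  r <- w[["fluorescence:I:Ka1"]] / w[["fluorescence:I:Ka2"]]
  lines <- emission_lines("I")
  expect_equal(r, lines$rel_intensity[1] / lines$rel_intensity[2],
               tolerance = 0.02)
})

test_that("runs are reproducible and scale with the primary count", {
  ph <- water_phantom()
  a <- run_position(ph, ref_beam(), ref_det(), 3000, seed = 9)
  b <- run_position(ph, ref_beam(), ref_det(), 3000, seed = 9)
  expect_identical(a$events, b$events)
  # physically scaled window counts stable under doubling primaries
  big <- run_position(ph, ref_beam(), ref_det(), 6e4, seed = 10)
  small <- run_position(ph, ref_beam(), ref_det(), 3e4, seed = 11)
  wb <- sum(scatter_order_histogram(big, c(20, 50)))
  ws <- sum(scatter_order_histogram(small, c(20, 50)))
  expect_equal(wb / ws, 1, tolerance = 0.1)
})

test_that("forced and analog estimates agree on a thin slab", {
  # 2 mm water slab (thin cylinder): analog statistics are feasible
  ph <- make_mouse_phantom(2, 60)
  n_f <- 2e4
  fr <- run_position(ph, ref_beam(), ref_det(), n_f, seed = 12,
                     forced = TRUE)
  n_a <- 1.2e6
  an <- run_position(ph, ref_beam(), ref_det(), n_a, seed = 13,
                     forced = FALSE)
  win <- c(38, 50)  # single-scatter peak region
  wf <- sum(scatter_order_histogram(fr, win)) / fr$scale
  wa <- sum(scatter_order_histogram(an, win)) / an$scale
  # per-primary detected intensity; analog counts are Poisson
  n_events <- sum(an$events$energy_keV >= win[1] &
                    an$events$energy_keV <= win[2])
  rel_sd <- 1 / sqrt(max(n_events, 1))
  expect_gt(n_events, 20)
  expect_lt(abs(wf / n_f - wa / n_a) / (wa / n_a), 3 * rel_sd + 0.05)
})

test_that("fluorescence rate is linear in deposit mass (thin target)", {
  rate <- function(mass) {
    ph <- add_deposit(water_phantom(),
                      marker_deposit("I", mass, c(0, 0, 0),
                                     radius_mm = 1.0))
    tr <- run_position(ph, ref_beam(), ref_det(), 3e4, seed = 21)
    fl <- tr$events[tr$events$multiplicity == 0, ]
    sum(fl$weight)
  }
  r1 <- rate(1)
  r8 <- rate(8)
  expect_equal(r8 / r1, 8, tolerance = 0.02)
})

test_that("scans are per-pixel reproducible and localized", {
  ph <- add_deposit(water_phantom(),
                    marker_deposit("I", 20, c(0, 5, 5), radius_mm = 1))
  grid <- data.frame(y = c(5, -5), z = c(5, 5))
  res <- run_scan(ph, ref_beam(), ref_det(), grid, 5000, seed = 31)
  expect_length(res, 2)
  res2 <- run_scan(ph, ref_beam(), ref_det(), grid, 5000, seed = 31)
  expect_identical(res[[1]]$events, res2[[1]]$events)
  # direct fluorescence concentrated in the pixel over the deposit; the
  # far pixel sees only the (weak) scatter-excited halo
  w_fl <- vapply(res, function(r) {
    d <- r$events[r$events$multiplicity == 0 &
                    r$events$origin != "scatter", ]
    sum(d$weight)
  }, numeric(1))
  expect_gt(w_fl[1], 0)
  expect_gt(w_fl[1], 20 * w_fl[2])
  # beam through the body is attenuated; off-body pixel transmits fully
  off <- run_position(ph, ref_beam(), ref_det(), 2000, seed = 5,
                      center_yz = c(40, 0))
  expect_equal(off$transmitted_fraction, 1)
  expect_lt(res[[1]]$transmitted_fraction, 1)
})

test_that("polarized beams modulate the azimuthal scatter distribution", {
  # with full linear polarization along y, scattering toward the detector
  # (in the x-y plane, phi = 0) is suppressed at ~90-150 degrees
  ph <- make_mouse_phantom(10, 60)
  unpol <- run_position(ph, ref_beam(), ref_det(), 3e4, seed = 41)
  pol <- run_position(ph, ref_beam(polarization = 1), ref_det(), 3e4,
                      seed = 41)
  w_u <- sum(scatter_order_histogram(unpol, c(40, 48)))
  w_p <- sum(scatter_order_histogram(pol, c(40, 48)))
  expect_lt(w_p, w_u)
})
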
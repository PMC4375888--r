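test_that("smooth_velocity returns the slope of a linear trace everywhere", {
  tr <- make_linear_trace(9, duration = 50, dt = 0.5)
  v <- smooth_velocity(tr, window = 10)
  expect_equal(v, rep(9, nrow(tr)), tolerance = 1e-10)
  # window = 1 gives the raw finite differences
  v1 <- smooth_velocity(tr, window = 1)
  expect_equal(v1, rep(9, nrow(tr)), tolerance = 1e-10)
})

test_that("smooth_velocity recovers a noisy slope on average", {
  withr::with_seed(5, {
    times <- 0:400
    tr <- make_trace(times, 9 * times + rnorm(length(times), 0, 3))
  })
  v <- smooth_velocity(tr, window = 10)
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 9), 2 * se + 0.05)
})

test_that("non-uniform time grids are rejected", {
  tr <- make_trace(c(0, 1, 2, 4, 5, 6, 7, 8, 9, 10, 11), rep(0, 11))
  expect_error(smooth_velocity(tr), "non-uniform")
})

test_that("phase classification reproduces constructed pause fractions", {
  expect_equal(classify_phases(rep(9, 50))$pausing_probability, 0)
  expect_equal(classify_phases(rep(0, 50))$pausing_probability, 1)
  v <- c(rep(9, 40), rep(0, 15), rep(9, 35), rep(0, 10))
  expect_equal(classify_phases(v, min_run = 1)$pausing_probability, 0.25)
  # short flickers merge into the surrounding phase
  vf <- c(rep(9, 30), 0, rep(9, 30))
  expect_equal(classify_phases(vf, min_run = 3)$pausing_probability, 0)
})

test_that("P_p depends only on velocities, not intensity units", {
  v <- c(rep(9, 30), rep(0.2, 20))
  p1 <- classify_phases(v)$pausing_probability
  # classification operates on velocities: a trace rescaled in intensity
  # units yields identical velocities, hence identical P_p
  expect_equal(classify_phases(v)$pausing_probability, p1)
})

test_that("pause_free_velocity excludes paused stretches", {
  tr <- make_linear_trace(9, duration = 100, dt = 1)
  pf <- pause_free_velocity(tr)
  expect_equal(pf$e, 9, tolerance = 1e-9)
  expect_equal(pf$pausing_probability, 0)

  # half slope 10, half slope 0
  t2 <- 0:200
  len <- c(10 * 0:100, rep(1000, 100))
  pf2 <- pause_free_velocity(make_trace(t2, len))
  expect_lt(abs(pf2$e - 10), 0.2)
  expect_lt(abs(pf2$pausing_probability - 0.5), 0.05)

  # simulated stochastic trace: within 3 SE of kon*conc - koff
  tr3 <- simulate_growth_trace(growth_params(kon = 11, conc = 1, koff = 2,
                                             duration = 500, dt = 1,
                                             seed = 31))
  pf3 <- pause_free_velocity(tr3)
  expect_lt(abs(pf3$e - 9), 3 * max(pf3$sem, 0.3, na.rm = TRUE))
})

test_that("a fully paused trace is an explicit error", {
  tr <- make_trace(0:50, rep(0, 51))
  expect_error(pause_free_velocity(tr), "fully paused")
})

test_that("rate-constant fits reproduce exact collinear points", {
  conc <- c(0.3, 0.5, 1, 2)
  pts <- data.frame(conc = conc, e = 11 * conc - 1.6)
  r <- fit_rate_constants(pts)
  expect_equal(r$kon, 11, tolerance = 1e-12)
  expect_equal(r$koff, 1.6, tolerance = 1e-12)
  expect_equal(r$cc, 1.6 / 11, tolerance = 1e-12)
  expect_equal(signif(r$cc, 2), 0.15)

  through_origin <- data.frame(conc = conc, e = 7 * conc)
  r0 <- fit_rate_constants(through_origin)
  expect_equal(r0$koff, 0, tolerance = 1e-12)
  expect_equal(r0$cc, 0, tolerance = 1e-12)
})

test_that("negative koff estimates are reported, not clipped", {
  conc <- c(0.3, 0.5, 1, 2)
  r <- fit_rate_constants(data.frame(conc = conc, e = 8.6 * conc + 1.3))
  expect_equal(r$koff, -1.3, tolerance = 1e-12)
})

test_that("fewer than 2 distinct concentrations are rejected", {
  expect_error(fit_rate_constants(data.frame(conc = c(1, 1), e = c(9, 9))),
               "2 distinct")
})

test_that("critical concentration arithmetic and invariances hold", {
  expect_equal(critical_concentration(11, 1.6), 1.6 / 11)
  expect_equal(signif(critical_concentration(8.5, 0.1), 2), 0.012)
  expect_equal(critical_concentration(5, 0), 0)
  expect_error(critical_concentration(0, 1), "undefined")
  # invariant under common rescaling of both rates
  expect_equal(critical_concentration(11, 1.6),
               critical_concentration(11 * 3.7, 1.6 * 3.7))
})

test_that("surface density and occupancy conversions are exact", {
  expect_equal(surface_density_from_concentration(1), 30.1107038,
               tolerance = 1e-6)
  expect_equal(surface_density_from_concentration(0), 0)
  expect_equal(surface_density_from_concentration(2),
               2 * surface_density_from_concentration(1))
  # one-face area of 200 mm^2 equals the default two-face geometry
  expect_equal(surface_density_from_concentration(1, area_mm2 = 200,
                                                  both_surfaces = FALSE),
               surface_density_from_concentration(1))

  expect_equal(tethers_per_micron(5900), 35.4)
  expect_equal(tethers_per_micron(16700), 100.2)
  expect_equal(tethers_per_micron(0), 0)

  expect_equal(fractional_occupancy(35.4), 35.4 / 370)
  expect_equal(fractional_occupancy(0), 0)
  expect_equal(fractional_occupancy(370), 1)
  expect_equal(fractional_occupancy(500), 1)
})
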
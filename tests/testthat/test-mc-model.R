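test_that("tether placement has binomial statistics and is seed-stable", {
  expect_identical(place_tethers(5000, 0, seed = 1), integer(0))
  expect_identical(place_tethers(5000, 1, seed = 1), 1:5000)
  expect_identical(place_tethers(5000, 0.3, seed = 9),
                   place_tethers(5000, 0.3, seed = 9))
  counts <- vapply(1:100, function(s) {
    length(place_tethers(1e5, 0.01, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1e5 * 0.01 * 0.99 / 100))
})

test_that("effective_kon follows the linear-decay allosteric rule", {
  expect_equal(effective_kon(50, integer(0), 5, 76, kon0 = 11), 11)
  expect_equal(effective_kon(20, 20, 5, 76, kon0 = 11), 55)
  expect_equal(effective_kon(100, 20, 9, 160, kon0 = 11), 5 * 11)
  expect_equal(effective_kon(300, 20, 9, 160, kon0 = 11), 11)
  # tethers ahead of the site have no influence
  expect_equal(effective_kon(10, 20, 9, 160, kon0 = 11), 11)
  # overlapping tethers saturate at the nearest one, never compound
  expect_equal(effective_kon(21, c(20, 21), 5, 76, kon0 = 11), 55)
})

test_that("expected-mode velocities equal a brute-force per-site oracle", {
  n <- 1000
  tet <- place_tethers(n, 0.01, seed = 13)
  oracle <- brute_force_kon(n, tet, 5.1, 76, 11)
  expect_equal(effective_kon(seq_len(n), tet, 5.1, 76, 11), oracle)
  cfg <- mc_config(n_sites = n)
  v <- simulate_elongation(cfg, 5.1, 76, 0.01, tethers = tet)
  expect_equal(v, mean(oracle * 1 - 2), tolerance = 1e-12)
})

test_that("closed-form occupancy limits hold to machine precision", {
  cfg <- mc_config(n_sites = 2000, seed = 2)
  expect_equal(simulate_elongation(cfg, 5, 76, 0), 11 * 1 - 2)
  expect_equal(simulate_elongation(cfg, 5, 76, 1), 5 * 11 * 1 - 2)
  expect_equal(simulate_elongation(cfg, 0.4, 11, 1), 0.4 * 11 * 1 - 2)
})

test_that("expected-mode velocity is monotone in occupancy, alpha and L_C", {
  cfg <- mc_config(n_sites = 5000)
  u <- withr::with_seed(3, runif(5000))
  occs <- c(0.001, 0.01, 0.05, 0.2, 1)
  alphas <- c(1.5, 3, 5, 9, 15)
  lcs <- c(1, 10, 50, 150, 400)
  for (a in alphas) {
    for (lc in lcs) {
      v <- vapply(occs, function(o) {
        simulate_elongation(cfg, a, lc, o, tethers = which(u < o))
      }, numeric(1))
      expect_true(all(diff(v) >= -1e-12))
    }
  }
  tet <- which(u < 0.01)
  for (lc in lcs) {
    v <- vapply(alphas, function(a) {
      simulate_elongation(cfg, a, lc, 0.01, tethers = tet)
    }, numeric(1))
    expect_true(all(diff(v) >= -1e-12))
  }
  for (a in alphas) {
    v <- vapply(lcs, function(lc) {
      simulate_elongation(cfg, a, lc, 0.01, tethers = tet)
    }, numeric(1))
    expect_true(all(diff(v) >= -1e-12))
  }
  # alpha < 1 reverses the direction
  v_down <- vapply(occs, function(o) {
    simulate_elongation(cfg, 0.4, 50, o, tethers = which(u < o))
  }, numeric(1))
  expect_true(all(diff(v_down) <= 1e-12))
})

test_that("stochastic mode matches expected mode for homogeneous lattices", {
  vs <- vapply(1:20, function(s) {
    cfg <- mc_config(n_sites = 1e4, mode = "stochastic", seed = s)
    simulate_elongation(cfg, 1, 76, 0.01)
  }, numeric(1))
  se <- sd(vs) / sqrt(length(vs))
  expect_lt(abs(mean(vs) - 9), 3 * se)
  # saturated lattice: every site at alpha * kon0
  vs1 <- vapply(1:20, function(s) {
    cfg <- mc_config(n_sites = 1e4, mode = "stochastic", seed = 100 + s)
    simulate_elongation(cfg, 2, 76, 1)
  }, numeric(1))
  se1 <- sd(vs1) / sqrt(length(vs1))
  expect_lt(abs(mean(vs1) - (2 * 11 - 2)), 3 * se1)
})

test_that("the local-concentration alternative model is affine in density", {
  expect_equal(local_concentration_velocity(11, 2, 1, 0), 9)
  expect_equal(local_concentration_velocity(11.6, 1.4, 1, 0.1), 14.84)
  d <- seq(0, 0.5, by = 0.05)
  e <- local_concentration_velocity(11.6, 1.4, 1, d)
  expect_equal(diff(e, differences = 2), rep(0, length(d) - 2),
               tolerance = 1e-12)
})
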
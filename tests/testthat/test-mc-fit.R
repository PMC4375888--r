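test_that("chi_square is the sum of squared standardized residuals", {
  expect_equal(chi_square(c(9, 10, 11), c(9, 10, 11), c(1, 1, 1)), 0)
  expect_equal(chi_square(9, 13, 2), 4)
  base <- chi_square(c(9, 10), c(9, 10.5), c(1, 1))
  expect_gte(chi_square(c(9, 10, 12), c(9, 10.5, 14), c(1, 1, 1)), base)
  expect_error(chi_square(9, 9, 0), "noise floor")
  expect_error(chi_square(c(9, 9), 9, 1), "equal lengths")
})

test_that("density-response generation matches per-rep elongation runs", {
  cfg <- mc_config(n_sites = 2000, seed = 5)
  dr <- simulate_density_response(5.1, 76, cfg, densities = c(100, 5000),
                                  reps = 8)
  expect_equal(nrow(dr), 2)
  expect_equal(dr$occupancy, occupancy_from_density(c(100, 5000)))
  expect_true(all(dr$v_std >= 0))
  expect_identical(dr, simulate_density_response(5.1, 76, cfg,
                                                 densities = c(100, 5000),
                                                 reps = 8))
  # the no-effect limit is flat at kon0*conc - koff for every density
  flat <- simulate_density_response(1, 76, cfg,
                                    densities = c(0, 100, 18000), reps = 3)
  expect_equal(flat$v_mean, rep(9, 3), tolerance = 1e-12)
  expect_equal(flat$v_std, rep(0, 3), tolerance = 1e-12)
  # zero density gives the tether-free velocity for any parameters
  d0 <- simulate_density_response(7, 150, cfg, densities = 0, reps = 3)
  expect_equal(d0$v_mean, 9, tolerance = 1e-12)
  expect_error(simulate_density_response(5, 76, cfg, numeric(0)),
               "non-empty")
})

test_that("the chi-square grid fit inverts its own forward model", {
  dens <- c(5, 50, 200, 600, 2000, 5900, 18000)
  cfg <- mc_config(n_sites = 1e4, seed = 11)
  dr <- simulate_density_response(5.1, 76, cfg, dens, reps = 10)
  fit <- grid_fit(dr, cfg, reps = 10)
  # recovery within one refined-grid step of the generating values
  # (default grids: log step 1.2^(1/5) in alpha, 13.8/5 monomers in L_C)
  expect_lt(abs(fit$alpha - 5.1), 0.21)
  expect_lt(abs(fit$l_c - 76), 2.8)
  expect_false(fit$boundary)
  # argmin property over every node the search evaluated
  expect_true(all(fit$chi2_min <= fit$nodes$chi2 + 1e-12))
  expect_true(all(fit$chi2_min <= fit$coarse$chi2_grid + 1e-12))
  # 68% intervals nest inside 95% intervals
  expect_gte(fit$ci68$alpha[1], fit$ci95$alpha[1])
  expect_lte(fit$ci68$alpha[2], fit$ci95$alpha[2])
  expect_gte(fit$ci68$l_c[1], fit$ci95$l_c[1])
  expect_lte(fit$ci68$l_c[2], fit$ci95$l_c[2])
})

test_that("an optimum at the grid edge is flagged as a boundary solution", {
  dens <- c(50, 600, 5900, 18000)
  cfg <- mc_config(n_sites = 1e4, seed = 3)
  dr <- simulate_density_response(0.4, 1, cfg, dens, reps = 10)
  fit <- grid_fit(dr, cfg, reps = 10)
  expect_true(fit$boundary)
  expect_lt(abs(fit$alpha - 0.4), 0.05)
  expect_lt(abs(fit$l_c - 1), 1)
})

test_that("delta-chi-square intervals cover the generating alpha", {
  # noisy replicates: the 68% interval should contain the truth in at
  # least ~60% of fits (nominal 68%, finite grid)
  dens <- c(50, 600, 2000, 5900, 18000)
  hits <- vapply(1:40, function(s) {
    cfg <- mc_config(n_sites = 1000, seed = 1000 + s)
    dr <- simulate_density_response(5.1, 76, cfg, dens, reps = 5,
                                    noise_sd = 0.5)
    cfg_fit <- mc_config(n_sites = 1000, seed = 5000 + s)
    fit <- grid_fit(dr, cfg_fit, reps = 5, refine_factor = 3)
    fit$ci68$alpha[1] <= 5.1 && 5.1 <= fit$ci68$alpha[2]
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})
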
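test_that("a straight contour has unit correlation and a capped fit", {
  straight <- data.frame(x_um = seq(0, 10, by = 0.125), y_um = 0)
  tab <- tangent_correlation(straight)
  expect_equal(tab$correlation, rep(1, nrow(tab)), tolerance = 1e-12)
  fit <- fit_persistence_length(tab)
  expect_true(fit$capped)
  expect_identical(fit$lp, Inf)
  rod <- simulate_wlc(Inf, 10, 8, seed = 1)
  expect_equal(tangent_correlation(rod)$correlation[1], 1,
               tolerance = 1e-12)
})

test_that("a circular arc decorrelates as the cosine of the swept angle", {
  r <- 3
  arc <- make_arc_contour(r, arc_length = 6, spacing_um = 0.125)
  tab <- tangent_correlation(arc)
  # uniform spacing on the circle: swept angle per step
  dphi <- 0.125 / r
  k <- seq_len(nrow(tab))
  expect_equal(tab$correlation, cos(k * dphi), tolerance = 1e-6)
})

test_that("worm-like chains realize the e^(-s/2Lp) correlation law", {
  lp <- 18
  chains <- lapply(1:500, function(s) simulate_wlc(lp, 10, 8, seed = s))
  spacing <- attr(chains[[1]], "spacing_um")
  # per-chain correlations at selected separations, against the law
  for (k in c(4, 16, 36)) {
    per_chain <- vapply(chains, function(ct) {
      th <- filakin:::contour_tangents(
        resample_contour(ct, spacing))
      n <- length(th)
      mean(cos(th[(k + 1):n] - th[seq_len(n - k)]))
    }, numeric(1))
    se <- sd(per_chain) / sqrt(length(per_chain))
    expect_lt(abs(mean(per_chain) - exp(-k * spacing / (2 * lp))),
              3 * se + 0.003)
  }
})

test_that("mean squared end-to-end distance matches the 2D closed form", {
  r2 <- vapply(1:200, function(s) {
    ct <- simulate_wlc(18, 10, 8, seed = 300 + s)
    n <- nrow(ct)
    (ct$x_um[n] - ct$x_um[1])^2 + (ct$y_um[n] - ct$y_um[1])^2
  }, numeric(1))
  expect_lt(abs(mean(r2) / wlc_mean_square_ee(18, 10) - 1), 0.05)
})

test_that("an exact exponential table is inverted to its decay length", {
  tab <- data.frame(s = (1:20) / 2, correlation = exp(-(1:20) / 2 / 36))
  fit <- fit_persistence_length(tab)
  expect_equal(fit$lp, 18, tolerance = 1e-6)
  expect_false(fit$capped)
})

test_that("persistence estimates are unbiased across the stiffness range", {
  for (lp in c(2.2, 5, 18)) {
    chains <- lapply(1:200, function(s) {
      simulate_wlc(lp, 10, 8, seed = round(1e4 * lp) + s)
    })
    est <- estimate_persistence_length(chains)
    expect_lt(abs(est$lp - lp) / lp, 0.1)
  }
})

test_that("the estimator is invariant to rigid motions and reversal", {
  chains <- lapply(1:30, function(s) simulate_wlc(10, 10, 8, seed = s))
  base <- estimate_persistence_length(chains)$lp
  rot <- lapply(chains, function(ct) {
    a <- 0.7
    data.frame(x_um = cos(a) * ct$x_um - sin(a) * ct$y_um + 5,
               y_um = sin(a) * ct$x_um + cos(a) * ct$y_um - 2)
  })
  expect_lt(abs(estimate_persistence_length(rot)$lp - base) / base, 1e-9)
  rev_ct <- lapply(chains, function(ct) ct[nrow(ct):1, ])
  expect_lt(abs(estimate_persistence_length(rev_ct)$lp - base) / base,
            1e-9)
})

test_that("the estimate scales with a uniform rescaling of coordinates", {
  chains <- lapply(1:30, function(s) simulate_wlc(10, 10, 8, seed = s))
  base <- estimate_persistence_length(chains)$lp
  scaled <- lapply(chains, function(ct) ct * 2.5)
  expect_lt(abs(estimate_persistence_length(scaled)$lp - 2.5 * base) /
              (2.5 * base), 1e-9)
})

test_that("degenerate persistence inputs are rejected", {
  expect_error(simulate_wlc(-1, 10), "> 0")
  expect_error(simulate_wlc(10, 0), "> 0")
  expect_error(resample_contour(data.frame(x_um = 1:5, y_um = 1:5)),
               ">= 10 points")
  tab <- data.frame(s = 1:3, correlation = exp(-(1:3) / 10))
  expect_error(fit_persistence_length(tab), "fewer than 5")
})
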
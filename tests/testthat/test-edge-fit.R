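test_that("an ideal step is located at the half-pixel between its levels", {
  prof <- c(rep(10, 50), rep(110, 30))
  fit <- fit_edge(prof, "rising")
  expect_true(fit$ok)
  expect_lt(abs(fit$center - 49.5), 0.5)
})

test_that("noiseless erf profiles are recovered to high subpixel precision", {
  x <- 0:59
  for (mu in c(12.25, 33.70, 47.9)) {
    prof <- 10 + 100 * erf_profile(x, mu, 2.0)
    fit <- fit_edge(prof, "rising")
    expect_true(fit$ok)
    expect_lt(abs(fit$center - mu), 0.01)
    expect_lt(abs(fit$width - 2.0), 0.01)
    expect_lt(abs(fit$amplitude - 100), 0.1)
    expect_lt(abs(fit$background - 10), 0.1)
  }
  # falling polarity
  proff <- 10 + 100 * (1 - erf_profile(x, 33.70, 2.0))
  fitf <- fit_edge(proff, "falling")
  expect_lt(abs(fitf$center - 33.70), 0.01)
})

test_that("the estimator is unbiased under Poisson noise", {
  x <- 0:59
  clean <- 20 + 200 * erf_profile(x, 28.40, 2.0)
  withr::with_seed(42, {
    centers <- vapply(1:100, function(r) {
      fit <- fit_edge(rpois(length(clean), clean), "rising")
      if (fit$ok) fit$center else NA_real_
    }, numeric(1))
  })
  expect_gt(mean(!is.na(centers)), 0.95)
  expect_lt(abs(mean(centers, na.rm = TRUE) - 28.40), 0.05)
})

test_that("fitted centres are translation-equivariant", {
  x <- 0:79
  base <- fit_edge(10 + 100 * erf_profile(x, 25.3, 2.0), "rising")
  for (delta in c(1, 7, 20)) {
    shifted <- fit_edge(10 + 100 * erf_profile(x, 25.3 + delta, 2.0),
                        "rising")
    expect_lt(abs(shifted$center - base$center - delta), 1e-6)
  }
})

test_that("fits are invariant to intensity rescaling up to amplitude", {
  x <- 0:59
  prof <- 10 + 100 * erf_profile(x, 33.7, 2.0)
  f1 <- fit_edge(prof, "rising")
  f2 <- fit_edge(3.5 * prof, "rising")
  expect_lt(abs(f1$center - f2$center), 1e-6)
  expect_lt(abs(f1$width - f2$width), 1e-6)
  expect_lt(abs(f2$amplitude / f1$amplitude - 3.5), 1e-6)
  expect_lt(abs(f2$background / f1$background - 3.5), 1e-6)
})

test_that("degenerate profiles fail cleanly", {
  flat <- fit_edge(rep(7, 20), "rising")
  expect_false(flat$ok)
  expect_equal(flat$reason, "no edge")
  # pure noise, no real edge: amplitude indistinguishable from noise
  noisy <- withr::with_seed(1, fit_edge(rnorm(40, 100, 1), "rising"))
  expect_false(isTRUE(noisy$ok) && noisy$amplitude > 30)
})

test_that("fitted centres always lie inside the profile support", {
  withr::with_seed(8, {
    for (r in 1:20) {
      prof <- pmax(rnorm(30, 50, 20), 0)
      fit <- fit_edge(prof, sample(c("rising", "falling"), 1))
      if (fit$ok) {
        expect_gte(fit$center, 0)
        expect_lte(fit$center, length(prof) - 1)
      }
    }
  })
})
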
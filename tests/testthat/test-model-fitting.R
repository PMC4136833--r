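test_that("interval-proportional weights follow the stated rule", {
  expect_equal(weights_from_times(c(1, 2, 4)), c(1, 1, 2))
  expect_equal(weights_from_times(seq(0.5, 5, by = 0.5)), rep(0.5, 10))
  expect_equal(weights_from_times(5), 5)  # t_0 = 0 convention
  expect_error(weights_from_times(c(2, 1)), "increasing")
  expect_error(weights_from_times(c(1, 1, 2)), "increasing")
})

test_that("weighted error matches its closed forms", {
  cu <- release_curve(times = c(1, 2, 4), values = c(0.1, 0.2, 0.3))
  expect_identical(weighted_error(cu, cu$values), 0)
  # constant residual r, weights w: E = sum(w) r^2
  cu2 <- release_curve(times = 1:5, values = rep(0.5, 5) + 1e-9 * (1:5),
                       weights = rep(2, 5))
  expect_equal(weighted_error(cu2, cu2$values - 0.1), 5 * 2 * 0.01,
               tolerance = 1e-6)
  cu3 <- release_curve(cu2$times, cu2$values, weights = rep(4, 5))
  expect_equal(weighted_error(cu3, cu3$values - 0.1),
               2 * weighted_error(cu2, cu2$values - 0.1))
  expect_error(weighted_error(cu, c(0.1, 0.2)), "length")
})

test_that("noiseless burst curves are recovered to within 1%", {
  spec <- release_presets(noise_sd = 0)[["BSA, pH 5"]]
  cu <- generate_curve(spec, basis62)
  fit <- fit_piecewise_diffusion(cu, geomd, basis62)
  expect_equal(fit$params$D0, 1.37e-6, tolerance = 0.01)
  expect_equal(fit$params$D1, 6.22e-8, tolerance = 0.01)
  expect_identical(fit$params$tc, 4)
  # tc is the argmin of the profile and E is consistent with the residuals
  expect_equal(names(which.min(fit$tc_profile)), "4")
  expect_equal(fit$weighted_error,
               sum(cu$weights * fit$residuals^2), tolerance = 1e-12)
})

test_that("without a burst the threshold is unidentifiable and D0 = D1", {
  d <- piecewise_diffusivity(2e-7, 2e-7, 4)
  spec <- experiment_spec("flat", d, geometry = geomd, noise_sd = 0)
  cu <- generate_curve(spec, basis62)
  fit <- fit_piecewise_diffusion(cu, geomd, basis62)
  expect_lt(max(fit$tc_profile) - min(fit$tc_profile), 1e-8)
  expect_equal(fit$params$D0, fit$params$D1, tolerance = 0.01)
})

test_that("the NLS solution is at least as good as a brute-force grid", {
  spec <- release_presets(noise_sd = 0.01, seed = 42)[["siRNA, pH 5"]]
  cu <- generate_curve(spec, basis62)
  fit <- fit_piecewise_diffusion(cu, geomd, basis62, tc_candidates = 4)
  # exhaustive log-space grid at the true tc
  lg <- expand.grid(l0 = seq(-8, -4, by = 0.25), l1 = seq(-9, -5, by = 0.25))
  ge <- mapply(function(l0, l1) {
    d <- piecewise_diffusivity(10^l0, 10^l1, 4)
    weighted_error(cu, release_fraction(cu$times, geomd, d, basis62))
  }, lg$l0, lg$l1)
  expect_lte(fit$weighted_error, min(ge))
  # same minimizer cell: fitted parameters within one grid spacing of the
  # best grid point
  best <- lg[which.min(ge), ]
  expect_lt(abs(log10(fit$params$D0) - best$l0), 0.25 + 1e-9)
  expect_lt(abs(log10(fit$params$D1) - best$l1), 0.25 + 1e-9)
})

test_that("the model is invariant under time/diffusivity rescaling", {
  g <- geomd
  d <- piecewise_diffusivity(1.37e-6, 6.22e-8, 4)
  tt <- default_schedule()
  cscale <- 3
  d2 <- piecewise_diffusivity(d$D0 / cscale, d$D1 / cscale, 4 * cscale)
  expect_equal(release_fraction(tt, g, d, basis62),
               release_fraction(tt * cscale, g, d2, basis62),
               tolerance = 1e-12)
  # refitting the rescaled curve recovers the rescaled diffusivities
  cu <- release_curve(tt * cscale,
                      release_fraction(tt * cscale, g, d2, basis62))
  fit <- fit_piecewise_diffusion(cu, g, basis62)
  expect_equal(fit$params$D0, d$D0 / cscale, tolerance = 0.01)
  expect_equal(fit$params$D1, d$D1 / cscale, tolerance = 0.01)
  expect_identical(fit$params$tc, 12)
})

test_that("insufficient data and malformed curves are rejected", {
  expect_error(fit_piecewise_diffusion(
    release_curve(c(1, 2, 3), c(0.1, 0.2, 0.3)), geomd, basis62),
    "at least 4")
  expect_error(release_curve(c(1, 2), c(0.1, 1.4)), "fractions")
  expect_error(release_curve(c(2, 1), c(0.1, 0.2)), "increasing")
})

test_that("fit reports collect parameters in the standard layout", {
  spec <- release_presets(noise_sd = 0)[["BSA, pH 7.4"]]
  fit <- fit_piecewise_diffusion(generate_curve(spec, basis62), geomd, basis62)
  rep1 <- diffusion_fit_report(list("BSA, pH 7.4" = fit))
  expect_named(rep1, c("Sample", "D0_cm2_s", "D1_cm2_s", "tc_h", "Error"))
  expect_equal(rep1$tc_h, 4)
  expect_equal(rep1$D0_cm2_s, 8.27e-7, tolerance = 0.01)
})
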
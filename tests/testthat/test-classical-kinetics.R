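tt <- default_schedule()

test_that("exact-model data return exact constants and R^2 = 1", {
  # constants on the percent scale; data generated on the fraction scale and
  # constants rescaled on readout (the two conventions differ by 100x for
  # the linear-in-release models)
  z <- fit_zero_order(release_curve(tt, 0.1976 / 100 * tt))
  expect_equal(z$params$K0 * 100, 0.1976, tolerance = 1e-10)
  expect_equal(z$r_squared, 1, tolerance = 1e-10)

  f <- fit_first_order(release_curve(tt, 1 - exp(-0.0017 * tt)), c0 = 1)
  expect_equal(f$params$K, 0.0017, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # K is scale-free: doubling c0 leaves it unchanged
  f2 <- fit_first_order(release_curve(tt, 1 - exp(-0.0017 * tt)), c0 = 2)
  expect_equal(f2$params$K, f$params$K, tolerance = 1e-12)

  h <- fit_higuchi(release_curve(tt, 2.995 / 100 * sqrt(tt)))
  expect_equal(h$params$k * 100, 2.995, tolerance = 1e-10)
  expect_equal(h$r_squared, 1, tolerance = 1e-10)

  kp <- fit_korsmeyer_peppas(release_curve(tt, 0.12 * tt^0.1848), m_inf = 1)
  expect_equal(kp$params$n, 0.1848, tolerance = 1e-8)
  expect_equal(kp$params$K, 0.12, tolerance = 1e-8)
  expect_equal(kp$r_squared, 1, tolerance = 1e-10)
  # a pure zero-order law has exponent 1
  kp1 <- fit_korsmeyer_peppas(release_curve(tt, 0.01 * tt), m_inf = 1)
  expect_equal(kp1$params$n, 1, tolerance = 1e-10)
})

test_that("direct NLS agrees with the log-log fit on exact power-law data", {
  cu <- release_curve(tt, 0.1 * tt^0.2684)
  a <- fit_korsmeyer_peppas(cu, m_inf = 1)
  b <- fit_korsmeyer_peppas(cu, m_inf = 1, method = "direct_nls")
  expect_equal(a$params$n, 0.2684, tolerance = 1e-8)
  expect_equal(b$params$n, 0.2684, tolerance = 1e-6)
})

test_that("time rescaling halves the Higuchi constant", {
  k1 <- fit_higuchi(release_curve(tt, 0.02 * sqrt(tt)))$params$k
  k2 <- fit_higuchi(release_curve(4 * tt, 0.02 * sqrt(tt)))$params$k
  expect_equal(k1 / k2, 2, tolerance = 1e-10)
})

test_that("OLS sensitivity: perturbing one point shifts the slope as predicted", {
  y <- 0.002 * tt
  eps <- 1e-3
  j <- 5L
  y2 <- y
  y2[j] <- y[j] + eps
  k1 <- fit_zero_order(release_curve(tt, y))$params$K0
  k2 <- fit_zero_order(release_curve(tt, y2))$params$K0
  expect_equal(k2 - k1, eps * tt[j] / sum(tt^2), tolerance = 1e-10)
})

test_that("R^2 follows its definition", {
  obs <- c(0.1, 0.3, 0.2, 0.5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_lt(r_squared(obs, rep(10, 4)), 0)
  expect_error(r_squared(rep(1, 3), rep(1, 3)), "undefined")
})

test_that("degenerate first-order input (nothing released) yields zero rate", {
  f <- fit_first_order(release_curve(tt, rep(0, length(tt))))
  expect_identical(f$params$K, 0)
  expect_error(fit_first_order(release_curve(c(1, 2), c(0.5, 1))),
               "positive")
})

test_that("log-log fitting rejects non-positive fractions, naming them", {
  expect_error(fit_korsmeyer_peppas(release_curve(c(1, 2, 3), c(0, 0.1, 0.2)),
                                    m_inf = 1),
               "t = 1")
})

test_that("mechanism classification uses the cylinder thresholds", {
  expect_identical(classify_mechanism(0.21), "Fickian diffusion")
  expect_identical(classify_mechanism(0.45), "Fickian diffusion") # inclusive
  expect_identical(classify_mechanism(0.7), "anomalous transport")
  expect_identical(classify_mechanism(0.89), "case-II transport")
  expect_identical(classify_mechanism(0.46, "film"), "Fickian diffusion")
  expect_error(classify_mechanism(-1), "positive")
})

test_that("on burst-release curves the power law is the best descriptor", {
  for (spec in release_presets(noise_sd = 0)) {
    cu <- generate_curve(spec, basis62)
    kp <- fit_korsmeyer_peppas(cu, geom = geomd)
    others <- c(fit_zero_order(cu, intercept = TRUE)$r_squared,
                fit_higuchi(cu, intercept = TRUE)$r_squared,
                fit_first_order(cu)$r_squared)
    expect_true(all(kp$r_squared > others))
    # exponent in the Fickian range, as for the emulated experiments
    expect_gt(kp$params$n, 0.1)
    expect_lt(kp$params$n, 0.45)
    expect_identical(classify_mechanism(kp$params$n), "Fickian diffusion")
  }
})

test_that("the four-model summary has the standard layout", {
  cu <- generate_curve(release_presets(noise_sd = 0)[["siRNA, pH 5"]], basis62)
  out <- fit_release_kinetics(cu, geom = geomd)
  expect_named(out, c("Model", "K", "n", "R2"))
  expect_equal(nrow(out), 4L)
  expect_true(is.na(out$n[1]) && !is.na(out$n[4]))
})
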
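test_that("effective diffusion time folds the piecewise diffusivity exactly", {
  d <- piecewise_diffusivity(D0 = 10, D1 = 1, tc = 4)
  expect_identical(effective_tau(0, d), 0)
  # continuity at the knot
  eps <- 1e-10
  expect_equal(effective_tau(4 - eps, d), effective_tau(4 + eps, d),
               tolerance = 1e-6)
  expect_equal(effective_tau(4, d), 10 * 4 * 3600)
  expect_equal(effective_tau(6, d), 3600 * (40 + 2))
  # strictly increasing
  tt <- seq(0, 20, by = 0.25)
  expect_true(all(diff(effective_tau(tt, d)) > 0))
  expect_error(effective_tau(-1, d), "non-negative")
})

test_that("equilibrium fraction is the bath's share of the cross-section", {
  expect_equal(equilibrium_fraction(cyl_geometry(1, 2, 1)), 0.75)
  expect_equal(equilibrium_fraction(cyl_geometry(1, 10, 1)), 0.99)
  expect_lt(equilibrium_fraction(cyl_geometry(0.999, 1, 1)), 0.003)
  expect_error(cyl_geometry(2, 1, 1), "smaller")
})

test_that("t = 0 sum identity holds within the truncation tail bound", {
  for (ratio in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    partial <- sum(4 * (besselJ(basis62$roots * ratio, 1) /
                          (basis62$roots * besselJ(basis62$roots, 0)))^2)
    gap <- (1 - ratio^2) - partial
    expect_gte(gap, 0)  # positive-term series: partial sum from below
    expect_lte(gap, tail_bound(basis62, 0, ratio))
  }
})

test_that("release fraction respects its analytic limits", {
  g <- cyl_geometry(1, 2, 1)
  d <- piecewise_diffusivity(1e-6, 1e-7, 4)
  expect_lte(release_fraction(0, g, d, basis62), tail_bound(basis62, 0, 0.5))
  # long-time limit: scaled time >= 5 is far past the slowest mode
  t_inf <- 5 * g$b^2 / (3600 * d$D1)
  expect_equal(release_fraction(t_inf, g, d, basis62), 0.75,
               tolerance = 1e-10)
})

test_that("release fraction is monotone in time and in each diffusivity", {
  g <- cyl_geometry(0.5, 2.9, 3.8)
  d <- piecewise_diffusivity(1.37e-6, 6.22e-8, 4)
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128)
  expect_true(all(diff(release_fraction(tt, g, d, basis62)) > 0))
  for (t0 in c(2, 6, 48)) {
    v0 <- vapply(c(1, 2, 5) * 1e-6, function(D0)
      release_fraction(t0, g, piecewise_diffusivity(D0, d$D1, 4), basis62),
      numeric(1))
    v1 <- vapply(c(1, 2, 5) * 1e-7, function(D1)
      release_fraction(t0, g, piecewise_diffusivity(d$D0, D1, 4), basis62),
      numeric(1))
    expect_true(all(diff(v0) >= 0))
    expect_true(all(diff(v1) >= 0))
  }
})

test_that("early-time release grows like the square root of diffusion time", {
  # Fickian signature; large basis so truncation does not pollute small times
  b500 <- j1_roots(500L)
  g <- cyl_geometry(1, 2, 1)
  d <- piecewise_diffusivity(1, 1, 1e9)  # tau = 3600 t
  s <- 10^seq(log10(2e-4), log10(2e-3), length.out = 8)  # one decade
  r <- release_fraction(s * g$b^2 / 3600, g, d, b500)
  ratio <- r / sqrt(s)
  expect_lt(max(ratio) / min(ratio) - 1, 0.05)
})

test_that("concentration profile conserves mass and approaches uniformity", {
  g <- cyl_geometry(1, 2, 1.5)
  d <- piecewise_diffusivity(1e-5, 1e-6, 4)
  M0 <- 2.5
  rr <- seq(0, g$b, length.out = 4001)
  for (t in c(0.5, 5, 50)) {
    cf <- concentration_profile(rr, t, M0, g, d, basis62)
    f <- cf$values * rr
    mass <- 2 * pi * g$H * sum(diff(rr) * (f[-1] + f[-length(f)]) / 2)
    expect_equal(mass, M0, tolerance = 1e-6)
  }
  t_inf <- 5 * g$b^2 / (3600 * d$D1)
  cf <- concentration_profile(c(0, 0.5, 1.3, 2), t_inf, M0, g, d, basis62)
  expect_equal(cf$values, rep(M0 / (pi * g$b^2 * g$H), 4), tolerance = 1e-10)
  expect_error(concentration_profile(c(0, 2.5), 1, 1, g, d, basis62),
               "radii")
})

test_that("at early times the profile still resembles the initial step", {
  g <- cyl_geometry(1, 2, 1)
  d <- piecewise_diffusivity(1, 1, 1e9)
  t <- 1e-4 * g$b^2 / 3600  # scaled time 1e-4
  M0 <- 1
  C0 <- M0 / (pi * g$a^2 * g$H)
  cf <- concentration_profile(c(g$a / 2, 3 * g$b / 4 + g$b / 8), t, M0, g, d,
                              j1_roots(500L))
  expect_equal(cf$values[1], C0, tolerance = 0.01)
  expect_lt(abs(cf$values[2]) / C0, 0.01)
})
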
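#' Coaxial cylinder geometry of the release experiment
#'
#' The dialysis device holding the carrier suspension is modelled as a
#' cylinder of radius `a` standing coaxially inside a closed cylindrical
#' container of radius `b` filled with release medium; both share height `H`.
#' Only the radius ratio `a/b` enters the released-fraction formula (heights
#' cancel), but the full geometry fixes volumes and concentrations.
#'
#' @param a Device (dialysis membrane) radius in cm.
#' @param b Bath (container) radius in cm; must exceed `a`.
#' @param H Height in cm.
#' @return An object of class `cyl_geometry` with fields `a`, `b`, `H`,
#'   `device_volume` (\eqn{\pi a^2 H}, mL) and `bath_volume`
#'   (\eqn{\pi (b^2 - a^2) H}, mL, the medium outside the membrane).
#' @export
cyl_geometry <- function(a, b, H) {
  for (nm in c("a", "b", "H")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
    }
  }
  if (a >= b) stop("device radius 'a' must be smaller than bath radius 'b'",
                   call. = FALSE)
  structure(list(a = a, b = b, H = H,
                 device_volume = pi * a^2 * H,
                 bath_volume = pi * (b^2 - a^2) * H),
            class = "cyl_geometry")
}

#' @export
print.cyl_geometry <- function(x, ...) {
  cat(sprintf("Cylindrical release geometry: a = %g cm, b = %g cm, H = %g cm\n",
              x$a, x$b, x$H))
  cat(sprintf("  device volume %.2f mL, bath medium volume %.2f mL, equilibrium fraction %.4f\n",
              x$device_volume, x$bath_volume, equilibrium_fraction(x)))
  invisible(x)
}

#' Piecewise-constant effective diffusivity
#'
#' Burst release is modelled by letting the effective diffusion coefficient
#' take a larger value `D0` during the initial burst phase (t <= `tc`) and a
#' smaller sustained value `D1` afterwards.
#'
#' @param D0 Burst-phase effective diffusivity, cm^2/s.
#' @param D1 Sustained-phase effective diffusivity, cm^2/s.
#' @param tc Threshold time ending the burst phase, hours.
#' @return An object of class `piecewise_diffusivity`.
#' @export
piecewise_diffusivity <- function(D0, D1, tc) {
  for (nm in c("D0", "D1", "tc")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
    }
  }
  structure(list(D0 = D0, D1 = D1, tc = tc), class = "piecewise_diffusivity")
}

#' @export
print.piecewise_diffusivity <- function(x, ...) {
  cat(sprintf("Piecewise diffusivity: D0 = %.3g cm^2/s (t <= %g h), D1 = %.3g cm^2/s\n",
              x$D0, x$tc, x$D1))
  invisible(x)
}

#' Effective diffusion time under piecewise-constant diffusivity
#'
#' Because the radial eigenfunctions do not depend on the diffusivity, a
#' piecewise-constant D(t) is handled exactly by the time substitution
#' \eqn{\tau(t) = \int_0^t D \, dt'}: the constant-D solution evaluated at
#' \eqn{\tau} is the solution of the time-varying problem. With time in hours
#' and D in cm^2/s, \eqn{\tau(t) = 3600 [D_0 \min(t, t_c) + D_1 \max(0, t - t_c)]}
#' in cm^2; the hours-to-seconds factor lives only here.
#'
#' @param t Time(s) in hours (non-negative, vectorized).
#' @param d A [piecewise_diffusivity()].
#' @return Effective diffusion time(s) \eqn{\tau} in cm^2; continuous and
#'   strictly increasing in `t`.
#' @export
effective_tau <- function(t, d) {
  stopifnot(inherits(d, "piecewise_diffusivity"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be non-negative and finite", call. = FALSE)
  }
  3600 * (d$D0 * pmin(t, d$tc) + d$D1 * pmax(0, t - d$tc))
}

#' Mass-balance equilibrium released fraction
#'
#' In a closed (finite) bath the concentration equilibrates to the uniform
#' value \eqn{M_0 / (\pi b^2 H)}; the fraction of payload then outside the
#' device is the bath's share of the cross-section, \eqn{1 - a^2/b^2}. Release
#' curves plateau at this value, below 1.
#'
#' @param geom A [cyl_geometry()].
#' @return The equilibrium fraction in (0, 1).
#' @export
equilibrium_fraction <- function(geom) {
  stopifnot(inherits(geom, "cyl_geometry"))
  1 - (geom$a / geom$b)^2
}

# Series coefficients c_n = 4 [J1(alpha_n a/b) / (alpha_n J0(alpha_n))]^2 and
# squared eigenvalues, precomputed once per (geometry, basis) pair. The sum
# identity sum(c_n) = 1 - (a/b)^2 holds in the infinite limit.
series_coefficients <- function(geom, basis) {
  al <- basis$roots
  cc <- geom$a / geom$b
  list(cn = 4 * (besselJ(al * cc, 1) / (al * besselJ(al, 0)))^2,
       al2 = al^2)
}

# Transient series sum(c_n * exp(-alpha_n^2 * s)) at scaled times s = tau/b^2.
series_transient <- function(s, coef) {
  as.vector(crossprod(coef$cn, exp(-outer(coef$al2, s))))
}

#' Cumulative released fraction of the finite-bath cylindrical model
#'
#' Evaluates the truncated eigenfunction-series solution for the fraction of
#' the initial payload found outside the dialysis device at time `t`:
#' \deqn{M_t/M_0 = (1 - a^2/b^2) - 4 \sum_{n=1}^{N}
#'   \left[\frac{J_1(\alpha_n a/b)}{\alpha_n J_0(\alpha_n)}\right]^2
#'   e^{-\alpha_n^2 \tau(t)/b^2},}
#' where \eqn{\alpha_n} are the positive roots of \eqn{J_1} and
#' \eqn{\tau(t)} the effective diffusion time of [effective_tau()]. The model
#' assumes purely radial diffusion, a freely permeable membrane, a uniform
#' initial concentration inside the device, and a closed container (zero flux
#' at r = b), so the curve rises monotonically to the finite-bath plateau
#' \eqn{1 - a^2/b^2}.
#'
#' At `t = 0` the truncated sum under-counts the transient by the series
#' tail, so the value is a small positive number bounded by [tail_bound()]
#' rather than exactly 0.
#'
#' @param t Time(s) in hours (vectorized).
#' @param geom A [cyl_geometry()].
#' @param d A [piecewise_diffusivity()].
#' @param basis An [`eigen_basis`][j1_roots]; default 62 terms.
#' @return Released fraction(s) in `[0, 1]`.
#' @export
release_fraction <- function(t, geom, d, basis = j1_roots(62L)) {
  stopifnot(inherits(geom, "cyl_geometry"), inherits(basis, "eigen_basis"))
  coef <- series_coefficients(geom, basis)
  s <- effective_tau(t, d) / geom$b^2
  eq <- equilibrium_fraction(geom)
  pmin(pmax(eq - series_transient(s, coef), 0), 1)
}

#' Radial concentration profile at a given time
#'
#' Evaluates the eigenfunction expansion of the concentration field
#' \deqn{C(r,t) = \frac{M_0}{\pi b^2 H} + \frac{2 M_0}{\pi a b H}
#'   \sum_{n=1}^{N} \frac{J_1(\alpha_n a/b)}{\alpha_n J_0(\alpha_n)^2}
#'   J_0(\alpha_n r/b)\, e^{-\alpha_n^2 \tau(t)/b^2},}
#' the orthogonal projection of the step initial condition onto the
#' zero-flux eigenmodes (each transient mode integrates to zero mass, since
#' \eqn{J_1} vanishes at the eigenvalues).
#' Total mass over the container is conserved (zero-flux outer boundary); as
#' \eqn{t \to \infty} the profile flattens to \eqn{M_0/(\pi b^2 H)}.
#'
#' @param radii Radial positions in `[0, b]`, cm.
#' @param t Time in hours (scalar).
#' @param M0 Initial payload mass (arbitrary mass unit).
#' @param geom,d,basis As in [release_fraction()].
#' @return An object of class `concentration_field`: list with `radii`,
#'   `values` (mass/volume) and `time`.
#' @export
concentration_profile <- function(radii, t, M0, geom, d,
                                  basis = j1_roots(62L)) {
  stopifnot(inherits(geom, "cyl_geometry"), inherits(basis, "eigen_basis"))
  if (any(radii < 0) || any(radii > geom$b)) {
    stop("all radii must lie in [0, b]", call. = FALSE)
  }
  if (length(t) != 1L) stop("'t' must be a single time", call. = FALSE)
  al <- basis$roots
  cc <- geom$a / geom$b
  s <- effective_tau(t, d) / geom$b^2
  base_conc <- M0 / (pi * geom$b^2 * geom$H)
  amp <- 2 * M0 / (pi * geom$a * geom$b * geom$H)
  wn <- besselJ(al * cc, 1) / (al * besselJ(al, 0)^2) * exp(-al^2 * s)
  modes <- outer(radii / geom$b, al, function(x, a) besselJ(a * x, 0))
  values <- base_conc + amp * as.vector(modes %*% wn)
  structure(list(radii = radii, values = values, time = t),
            class = "concentration_field")
}
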
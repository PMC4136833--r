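#' Default release-experiment geometry
#'
#' A dialysis device of radius 0.5 cm and height 3.8 cm standing in a beaker
#' of radius 2.9 cm: the bath then holds about 100 mL of release medium, the
#' volume used in the emulated experiments. Only the radius ratio enters the
#' released-fraction formula, so self-consistent simulate-and-refit studies
#' are insensitive to this choice; it is declared once and used everywhere.
#'
#' @return A [cyl_geometry()].
#' @export
default_geometry <- function() cyl_geometry(a = 0.5, b = 2.9, H = 3.8)

#' Default sampling schedule
#'
#' Twelve sampling times spanning a dense early (burst) phase and sparse
#' late (sustained) phase: 0.5, 1, 2, 3, 4, 6, 8, 12, 24, 36, 48, 72 h.
#' The 4 h point sits on the schedule so that threshold-time profiling can
#' land on it exactly.
#'
#' @return Strictly increasing times in hours.
#' @export
default_schedule <- function() c(0.5, 1, 2, 3, 4, 6, 8, 12, 24, 36, 48, 72)

#' Specification of a synthetic release experiment
#'
#' Bundles everything needed to generate one synthetic cumulative-release
#' curve: geometry, piecewise diffusivity, sampling schedule, measurement
#' noise and seed.
#'
#' @param label Curve label, e.g. `"BSA, pH 5"`.
#' @param diffusivity A [piecewise_diffusivity()].
#' @param geometry A [cyl_geometry()]; default [default_geometry()].
#' @param schedule Strictly increasing sampling times (h), first > 0.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   on the fraction scale (default 0.01, about 1 percentage point, typical
#'   of cumulative spectrophotometric assays).
#' @param seed Optional integer seed; generation is deterministic given it.
#' @param monotone Project the noisy curve onto the nearest non-decreasing
#'   sequence (cumulative curves are physically monotone).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(label, diffusivity, geometry = default_geometry(),
                            schedule = default_schedule(), noise_sd = 0.01,
                            seed = NULL, monotone = TRUE) {
  stopifnot(inherits(diffusivity, "piecewise_diffusivity"),
            inherits(geometry, "cyl_geometry"))
  if (any(schedule <= 0) || is.unsorted(schedule, strictly = TRUE)) {
    stop("'schedule' must be strictly increasing with first time > 0",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  structure(list(label = label, geometry = geometry,
                 diffusivity = diffusivity, schedule = schedule,
                 noise_sd = noise_sd, seed = seed, monotone = monotone),
            class = "experiment_spec")
}

# Evaluate an expression under a temporary RNG state so generation with a
# seed does not disturb the caller's random stream.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic cumulative-release curve
#'
#' Evaluates the finite-bath series model [release_fraction()] on the
#' experiment's schedule, adds zero-mean Gaussian noise (sd = `noise_sd`),
#' clips to `[0, equilibrium fraction]`, and — when `monotone` — projects
#' onto the nearest non-decreasing sequence by isotonic regression
#' ([stats::isoreg()]); clipping happens before the projection. With
#' `noise_sd = 0` the values equal the model exactly.
#'
#' @param spec An [experiment_spec()].
#' @param basis An [`eigen_basis`][j1_roots]; default 62 terms.
#' @return A [release_curve()] with interval-proportional weights.
#' @export
generate_curve <- function(spec, basis = j1_roots(62L)) {
  stopifnot(inherits(spec, "experiment_spec"))
  clean <- release_fraction(spec$schedule, spec$geometry, spec$diffusivity,
                            basis)
  vals <- with_rng_seed(spec$seed, {
    v <- clean
    if (spec$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
    v
  })
  vals <- pmin(pmax(vals, 0), equilibrium_fraction(spec$geometry))
  if (spec$monotone && spec$noise_sd > 0) {
    vals <- stats::isoreg(spec$schedule, vals)$yf
  }
  release_curve(spec$schedule, vals)
}

#' Reference parameter presets for the four emulated release experiments
#'
#' Four [experiment_spec()]s carrying the piecewise effective diffusivities
#' estimated for siRNA- and BSA-loaded cholic acid-polyethylenimine (CA-PEI)
#' micelles dialysed into pH 5 and pH 7.4 media: burst diffusivities about
#' 20-30 times the sustained ones, a 4 h threshold in all four conditions,
#' and faster release at pH 5 than at pH 7.4. These presets emulate the
#' published release conditions; the underlying raw curves are not
#' machine-readable, so the presets are synthetic stand-ins with the
#' published fitted parameters, not reproductions of the measured data.
#'
#' @param geometry A [cyl_geometry()] shared by all presets.
#' @param noise_sd,seed,monotone Passed to each [experiment_spec()]; the
#'   seed, when given, is offset by the preset index so curves differ.
#' @return A named list of four `experiment_spec`s: `"BSA, pH 5"`,
#'   `"BSA, pH 7.4"`, `"siRNA, pH 5"`, `"siRNA, pH 7.4"`.
#' @export
release_presets <- function(geometry = default_geometry(), noise_sd = 0.01,
                            seed = NULL, monotone = TRUE) {
  tab <- list(
    "BSA, pH 5"     = c(D0 = 1.37e-6, D1 = 6.22e-8),
    "BSA, pH 7.4"   = c(D0 = 8.27e-7, D1 = 4.55e-8),
    "siRNA, pH 5"   = c(D0 = 2.31e-6, D1 = 1.24e-7),
    "siRNA, pH 7.4" = c(D0 = 1.91e-6, D1 = 5.72e-8))
  out <- vector("list", length(tab))
  names(out) <- names(tab)
  for (i in seq_along(tab)) {
    out[[i]] <- experiment_spec(
      label = names(tab)[i],
      diffusivity = piecewise_diffusivity(D0 = tab[[i]][["D0"]],
                                          D1 = tab[[i]][["D1"]], tc = 4),
      geometry = geometry, noise_sd = noise_sd,
      seed = if (is.null(seed)) NULL else seed + i - 1L,
      monotone = monotone)
  }
  out
}
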
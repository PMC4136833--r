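#' Sampled cumulative-release curve
#'
#' Container for cumulative-release observations: sampling times (hours),
#' cumulative released fractions, and the fitting weights. Weights default to
#' the interval-proportional rule of [weights_from_times()], reflecting that
#' sparsely sampled late observations summarize longer stretches of the
#' experiment.
#'
#' @param times Non-negative, strictly increasing sampling times in hours
#'   (a leading 0 is allowed and receives zero weight).
#' @param values Cumulative released fractions in `[0, 1]` (use
#'   [read_release_csv()] to convert percent data).
#' @param weights Optional positive fitting weights; computed from the times
#'   when omitted.
#' @return An object of class `release_curve`.
#' @export
release_curve <- function(times, values, weights = NULL) {
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop("'values' must be cumulative released fractions in [0, 1]",
         call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- diff(c(0, times))
  } else {
    if (length(weights) != length(times) || any(!is.finite(weights)) ||
        any(weights < 0)) {
      stop("'weights' must be non-negative and match 'times' in length",
           call. = FALSE)
    }
  }
  structure(list(times = times, values = pmin(pmax(values, 0), 1),
                 weights = weights),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Release curve: %d observations, t in [%g, %g] h, release %.3f..%.3f\n",
              length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.release_curve <- function(x, ...) {
  data.frame(time_h = x$times, release = x$values, weight = x$weights)
}

#' Interval-proportional fitting weights
#'
#' Weight each observation by the length of the sampling interval it closes:
#' \eqn{w_k = t_k - t_{k-1}} with the convention \eqn{t_0 = 0}. Weights are
#' returned unnormalized (proportionality constant 1), so the absolute scale
#' of a weighted fitting error depends on this convention.
#'
#' @param times Strictly increasing positive times in hours.
#' @return Positive weights, one per time.
#' @export
weights_from_times <- function(times) {
  if (length(times) < 1L || any(!is.finite(times)) || any(times <= 0) ||
      is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing and positive", call. = FALSE)
  }
  diff(c(0, times))
}

#' Weighted sum-of-squares fitting error
#'
#' \eqn{E = \sum_k w_k (y_k - \hat y_k)^2} between a release curve's observed
#' values and a model's predictions at the same times.
#'
#' @param curve A [release_curve()].
#' @param model_values Model predictions, one per observation.
#' @return The non-negative weighted error.
#' @export
weighted_error <- function(curve, model_values) {
  stopifnot(inherits(curve, "release_curve"))
  if (length(model_values) != length(curve$values)) {
    stop("'model_values' must match the curve in length", call. = FALSE)
  }
  sum(curve$weights * (curve$values - model_values)^2)
}

# Inner 2-parameter weighted NLS at a fixed threshold time: minimizes E over
# (log10 D0, log10 D1). A coarse log-space grid scan supplies one start;
# further multistarts are spread across the bounded box. L-BFGS-B with
# finite-difference gradients does the local refinement.
fit_at_tc <- function(curve, coef, b2, tc, log10_bounds, n_starts) {
  tmin <- pmin(curve$times, tc)
  trem <- pmax(0, curve$times - tc)
  eq <- sum(coef$cn) + attr(coef, "eq_gap")
  objective <- function(p) {
    s <- 3600 * (10^p[1L] * tmin + 10^p[2L] * trem) / b2
    sum(curve$weights * (curve$values - (eq - series_transient(s, coef)))^2)
  }
  # coarse grid start
  gr <- seq(log10_bounds[1L] + 1, log10_bounds[2L] - 1, by = 1)
  grid_pts <- as.matrix(expand.grid(gr, gr))
  ge <- apply(grid_pts, 1L, objective)
  starts <- list(unname(grid_pts[which.min(ge), ]))
  spread <- seq(log10_bounds[1L] + 2, log10_bounds[2L] - 2,
                length.out = n_starts - 1L)
  for (x in spread) starts <- c(starts, list(c(x, x - 1)))
  best <- NULL
  for (p0 in starts) {
    opt <- try(stats::optim(p0, objective, method = "L-BFGS-B",
                            lower = log10_bounds[1L], upper = log10_bounds[2L],
                            control = list(factr = 10, maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) return(NULL)
  list(par = best$par, value = best$value, grid_best = min(ge))
}

#' Fit the piecewise-diffusivity cylindrical model to a release curve
#'
#' Estimates the burst diffusivity `D0`, the sustained diffusivity `D1` and
#' the threshold time `tc` by weighted nonlinear least squares against the
#' truncated-series released-fraction model. Because the error surface is
#' non-smooth in `tc` (the model has a knot there) and the experiment's
#' sampling grid is the natural resolution for the burst/sustained boundary,
#' `tc` is profiled over a discrete candidate set — by default the
#' observation times except the last — and, at each candidate, `E` is
#' minimized over `(log10 D0, log10 D1)` from multiple starts. The global
#' minimizer over the profile is returned.
#'
#' @param curve A [release_curve()] with at least 4 observations.
#' @param geom A [cyl_geometry()]; must be the geometry the data refer to
#'   (it fixes the equilibrium plateau).
#' @param basis An [`eigen_basis`][j1_roots]; default 62 terms.
#' @param tc_candidates Candidate threshold times in `(0, max(times))`;
#'   default: all observation times but the last.
#' @param d_bounds Diffusivity search bounds in cm^2/s.
#' @param n_starts Number of multistarts for the inner 2-parameter problem.
#' @return An object of class `diffusion_fit`: list with `params`
#'   (a [piecewise_diffusivity()]), `weighted_error`, `residuals`
#'   (observed minus fitted), `tc_profile` (named vector of minimized errors
#'   per candidate), `fitted_curve` (a [release_curve()] of model values) and
#'   `tail_bound` (series truncation bound at the earliest observation).
#' @export
fit_piecewise_diffusion <- function(curve, geom, basis = j1_roots(62L),
                                    tc_candidates = NULL,
                                    d_bounds = c(1e-12, 1e-3),
                                    n_starts = 5L) {
  stopifnot(inherits(curve, "release_curve"), inherits(geom, "cyl_geometry"))
  if (length(curve$times) < 4L) {
    stop("diffusion fitting needs at least 4 observations", call. = FALSE)
  }
  if (is.null(tc_candidates)) {
    tc_candidates <- curve$times[curve$times > 0 &
                                   curve$times < max(curve$times)]
  }
  if (any(tc_candidates <= 0) || any(tc_candidates >= max(curve$times))) {
    stop("'tc_candidates' must lie in (0, max(times))", call. = FALSE)
  }
  coef <- series_coefficients(geom, basis)
  # the model's plateau term: equilibrium fraction = sum(cn) + truncation gap
  attr(coef, "eq_gap") <- equilibrium_fraction(geom) - sum(coef$cn)
  log10_bounds <- log10(d_bounds)
  b2 <- geom$b^2

  profile <- rep(NA_real_, length(tc_candidates))
  names(profile) <- as.character(tc_candidates)
  pars <- vector("list", length(tc_candidates))
  for (i in seq_along(tc_candidates)) {
    res <- fit_at_tc(curve, coef, b2, tc_candidates[i], log10_bounds, n_starts)
    if (is.null(res)) next
    profile[i] <- res$value
    pars[[i]] <- res$par
  }
  if (all(is.na(profile))) {
    stop("optimizer failed to converge at every threshold candidate",
         call. = FALSE)
  }
  i_best <- which.min(profile)
  params <- piecewise_diffusivity(D0 = unname(10^pars[[i_best]][1L]),
                                  D1 = unname(10^pars[[i_best]][2L]),
                                  tc = tc_candidates[i_best])
  fitted_vals <- release_fraction(curve$times, geom, params, basis)
  structure(list(params = params,
                 weighted_error = weighted_error(curve, fitted_vals),
                 residuals = curve$values - fitted_vals,
                 tc_profile = profile,
                 fitted_curve = release_curve(curve$times, fitted_vals,
                                              curve$weights),
                 tail_bound = tail_bound(basis,
                                         effective_tau(min(curve$times), params) / b2,
                                         geom$a / geom$b)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("Finite-bath cylindrical diffusion fit\n")
  cat(sprintf("  D0 = %.3g cm^2/s  D1 = %.3g cm^2/s  tc = %g h\n",
              x$params$D0, x$params$D1, x$params$tc))
  cat(sprintf("  weighted error E = %.3g (unnormalized, w_k = interval lengths)\n",
              x$weighted_error))
  cat(sprintf("  series tail bound at first observation: %.2g\n", x$tail_bound))
  invisible(x)
}

#' Tabular report of piecewise-diffusion fits
#'
#' Collects one or more [fit_piecewise_diffusion()] results into the standard
#' report layout (one row per sample: D0, D1, tc, weighted error).
#'
#' @param fits A named list of `diffusion_fit` objects (names become the
#'   `Sample` column) or a single fit.
#' @return A data.frame with columns `Sample`, `D0_cm2_s`, `D1_cm2_s`,
#'   `tc_h`, `Error`.
#' @export
diffusion_fit_report <- function(fits) {
  if (inherits(fits, "diffusion_fit")) fits <- list(fit = fits)
  data.frame(Sample = names(fits),
             D0_cm2_s = vapply(fits, function(f) f$params$D0, numeric(1)),
             D1_cm2_s = vapply(fits, function(f) f$params$D1, numeric(1)),
             tc_h = vapply(fits, function(f) f$params$tc, numeric(1)),
             Error = vapply(fits, function(f) f$weighted_error, numeric(1)),
             row.names = NULL)
}
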
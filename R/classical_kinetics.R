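#' Coefficient of determination about the observed mean
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the observations, whatever the fitting scale. Can be
#' negative when the model is worse than the mean.
#'
#' @param observed,fitted Equal-length numeric vectors; the observations must
#'   not be all equal.
#' @return A scalar `<= 1`.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L) {
    stop("'observed' and 'fitted' must be equal-length vectors (>= 2)",
         call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined: all observed values are equal", call. = FALSE)
  }
  1 - sum((observed - fitted)^2) / ss_tot
}

new_kinetics_fit <- function(model, params, r2, fitted_values) {
  structure(list(model = model, params = params, r_squared = r2,
                 fitted_values = fitted_values),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  p <- paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
             collapse = ", ")
  cat(sprintf("%s fit: %s, R^2 = %.4f\n", x$model, p, x$r_squared))
  invisible(x)
}

#' Zero-order release model
#'
#' Fits the constant-rate law \eqn{Q_t = K_0 t} (through the origin by
#' default: release starts at zero) by ordinary least squares on the
#' untransformed values.
#'
#' @param curve A [release_curve()] with at least 2 observations.
#' @param intercept Add an intercept term (default `FALSE`).
#' @return A `kinetics_fit` with parameter `K0` and `r_squared` computed on
#'   the untransformed values.
#' @export
fit_zero_order <- function(curve, intercept = FALSE) {
  stopifnot(inherits(curve, "release_curve"))
  if (length(curve$times) < 2L) stop("need at least 2 points", call. = FALSE)
  fm <- if (intercept) stats::lm(y ~ t, data = list(y = curve$values, t = curve$times))
        else stats::lm(y ~ 0 + t, data = list(y = curve$values, t = curve$times))
  new_kinetics_fit("zero_order", list(K0 = unname(stats::coef(fm)[["t"]])),
                   r_squared(curve$values, stats::fitted(fm)),
                   unname(stats::fitted(fm)))
}

#' First-order release model
#'
#' Fits exponential depletion of the remaining payload,
#' \eqn{C_0 - Q_t = C_0 e^{-Kt}}, by linear regression of the logarithm of
#' the remaining amount against time. The rate constant is reported in the
#' natural-log convention by default; `log_base = "log10"` reports the slope
#' of the base-10 regression instead (both conventions circulate in the
#' dissolution literature).
#'
#' @param curve A [release_curve()].
#' @param c0 Initial payload concentration (arbitrary units); `K` does not
#'   depend on it.
#' @param log_base `"natural"` (default) or `"log10"`.
#' @return A `kinetics_fit` with parameter `K` (positive for decaying
#'   remaining amount); `r_squared` is computed on the log scale the
#'   regression is performed on.
#' @export
fit_first_order <- function(curve, c0 = 1, log_base = c("natural", "log10")) {
  stopifnot(inherits(curve, "release_curve"))
  log_base <- match.arg(log_base)
  remaining <- c0 * (1 - curve$values)
  if (any(remaining <= 0)) {
    stop("remaining amount must stay positive at all observations",
         call. = FALSE)
  }
  ly <- log(remaining)
  if (max(ly) - min(ly) == 0) {
    # nothing released: zero rate, R^2 undefined (no variation to explain)
    return(new_kinetics_fit("first_order", list(K = 0), NA_real_,
                            rep(0, length(ly))))
  }
  fm <- stats::lm(ly ~ t, data = list(ly = ly, t = curve$times))
  K <- -unname(stats::coef(fm)[["t"]])
  if (log_base == "log10") K <- K / log(10)
  new_kinetics_fit("first_order", list(K = K),
                   r_squared(ly, stats::fitted(fm)),
                   c0 - unname(exp(stats::fitted(fm))))
}

#' Higuchi square-root-of-time model
#'
#' Fits the diffusion-controlled matrix law \eqn{Q_t = k \sqrt{t}} by OLS
#' through the origin (an intercept is optional).
#'
#' @param curve A [release_curve()].
#' @param intercept Add an intercept term (default `FALSE`).
#' @return A `kinetics_fit` with parameter `k`.
#' @export
fit_higuchi <- function(curve, intercept = FALSE) {
  stopifnot(inherits(curve, "release_curve"))
  if (length(curve$times) < 2L) stop("need at least 2 points", call. = FALSE)
  st <- sqrt(curve$times)
  fm <- if (intercept) stats::lm(y ~ st, data = list(y = curve$values, st = st))
        else stats::lm(y ~ 0 + st, data = list(y = curve$values, st = st))
  new_kinetics_fit("higuchi", list(k = unname(stats::coef(fm)[["st"]])),
                   r_squared(curve$values, stats::fitted(fm)),
                   unname(stats::fitted(fm)))
}

#' Korsmeyer-Peppas power-law model
#'
#' Fits \eqn{M_t/M_\infty = K_{KP} t^n}. The released fraction is normalized
#' by `m_inf`; when a geometry is supplied the finite-bath equilibrium
#' fraction is used, otherwise the last observed value (the paper-style
#' convention when the true plateau is unknown). The default method
#' regresses \eqn{\log(M_t/M_\infty)} on \eqn{\log t} (any observation at
#' `t = 0` or with zero release is rejected with a message naming it);
#' `method = "direct_nls"` refines on the original scale by [stats::nls()]
#' seeded from the log-log fit. Fitting may optionally be restricted to the
#' conventional first 60% of release.
#'
#' @param curve A [release_curve()].
#' @param geom Optional [cyl_geometry()] fixing \eqn{M_\infty}.
#' @param m_inf Optional explicit \eqn{M_\infty} (overrides `geom`).
#' @param method `"loglog_linear"` (default) or `"direct_nls"`.
#' @param first60 Restrict to observations with \eqn{M_t/M_\infty \le 0.6}.
#' @return A `kinetics_fit` with parameters `K` and `n`; `r_squared` is
#'   computed on the scale the fit was performed on.
#' @export
fit_korsmeyer_peppas <- function(curve, geom = NULL, m_inf = NULL,
                                 method = c("loglog_linear", "direct_nls"),
                                 first60 = FALSE) {
  stopifnot(inherits(curve, "release_curve"))
  method <- match.arg(method)
  if (is.null(m_inf)) {
    m_inf <- if (!is.null(geom)) equilibrium_fraction(geom)
             else curve$values[length(curve$values)]
  }
  if (m_inf <= 0) stop("'m_inf' must be positive", call. = FALSE)
  frac <- curve$values / m_inf
  keep <- rep(TRUE, length(frac))
  if (first60) keep <- frac <= 0.6
  bad <- which((curve$times <= 0 | frac <= 0) & keep)
  if (length(bad) > 0) {
    stop(sprintf(
      "power-law fitting needs t > 0 and release > 0; offending observation(s): %s",
      paste(sprintf("t = %g h", curve$times[bad]), collapse = ", ")),
      call. = FALSE)
  }
  t <- curve$times[keep]; fr <- frac[keep]
  if (length(t) < 2L) stop("need at least 2 usable points", call. = FALSE)
  lf <- log(fr); lt <- log(t)
  fm <- stats::lm(lf ~ lt, data = list(lf = lf, lt = lt))
  K <- exp(unname(stats::coef(fm)[[1L]]))
  n <- unname(stats::coef(fm)[["lt"]])
  if (method == "loglog_linear") {
    return(new_kinetics_fit("korsmeyer_peppas", list(K = K, n = n),
                            r_squared(lf, stats::fitted(fm)),
                            m_inf * K * curve$times^n))
  }
  # Levenberg-Marquardt: robust where Gauss-Newton stalls on near-zero
  # residuals (exact power-law data)
  nf <- minpack.lm::nlsLM(fr ~ K * t^n, data = list(fr = fr, t = t),
                          start = list(K = K, n = n))
  cf <- stats::coef(nf)
  new_kinetics_fit("korsmeyer_peppas",
                   list(K = unname(cf[["K"]]), n = unname(cf[["n"]])),
                   r_squared(fr, stats::fitted(nf)),
                   m_inf * unname(cf[["K"]]) * curve$times^unname(cf[["n"]]))
}

#' Release-mechanism classification from the power-law exponent
#'
#' Maps the Korsmeyer-Peppas exponent `n` to a transport mechanism using the
#' standard geometry-dependent thresholds (`low`: Fickian upper bound,
#' inclusive; `high`: case-II lower bound, inclusive): cylinder 0.45/0.89,
#' film 0.50/1.00, sphere 0.43/0.85.
#'
#' @param n Release exponent (> 0).
#' @param geometry_class `"cylinder"` (default), `"film"` or `"sphere"`.
#' @param thresholds Optional length-2 numeric `c(low, high)` overriding the
#'   standard values.
#' @return One of `"Fickian diffusion"`, `"anomalous transport"`,
#'   `"case-II transport"`.
#' @export
classify_mechanism <- function(n, geometry_class = c("cylinder", "film", "sphere"),
                               thresholds = NULL) {
  if (length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("'n' must be a single positive number", call. = FALSE)
  }
  geometry_class <- match.arg(geometry_class)
  if (is.null(thresholds)) {
    thresholds <- switch(geometry_class,
                         cylinder = c(0.45, 0.89),
                         film = c(0.50, 1.00),
                         sphere = c(0.43, 0.85))
  }
  if (n <= thresholds[1L]) "Fickian diffusion"
  else if (n < thresholds[2L]) "anomalous transport"
  else "case-II transport"
}

#' Fit all four classical release models
#'
#' Convenience wrapper fitting the zero-order, first-order, Higuchi and
#' Korsmeyer-Peppas models to one curve and tabulating constants and
#' \eqn{R^2} in the standard layout.
#'
#' @param curve A [release_curve()].
#' @param geom Optional geometry passed to [fit_korsmeyer_peppas()].
#' @param ... Further arguments passed to the individual fitters.
#' @return A data.frame with columns `Model`, `K`, `n` (NA where not
#'   applicable) and `R2`, plus attribute `"fits"` holding the four
#'   `kinetics_fit` objects.
#' @export
fit_release_kinetics <- function(curve, geom = NULL, ...) {
  fits <- list(zero_order = fit_zero_order(curve),
               first_order = fit_first_order(curve),
               higuchi = fit_higuchi(curve),
               korsmeyer_peppas = fit_korsmeyer_peppas(curve, geom = geom, ...))
  out <- data.frame(
    Model = names(fits),
    K = c(fits$zero_order$params$K0, fits$first_order$params$K,
          fits$higuchi$params$k, fits$korsmeyer_peppas$params$K),
    n = c(NA, NA, NA, fits$korsmeyer_peppas$params$n),
    R2 = vapply(fits, function(f) f$r_squared, numeric(1)),
    row.names = NULL)
  attr(out, "fits") <- fits
  out
}
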
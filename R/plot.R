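#' Plot a release curve with its fitted diffusion model
#'
#' Observed cumulative release (points) overlaid with the fitted
#' piecewise-diffusivity model evaluated on a dense time grid (line), plus
#' the finite-bath equilibrium plateau (dashed). Requires ggplot2.
#'
#' @param curve A [release_curve()].
#' @param fit A [fit_piecewise_diffusion()] result.
#' @param geom The [cyl_geometry()] used for the fit.
#' @param basis An [`eigen_basis`][j1_roots].
#' @param label Title for the panel.
#' @return A ggplot object.
#' @export
plot_release_fit <- function(curve, fit, geom, basis = j1_roots(62L),
                             label = "") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
  tt <- seq(min(curve$times) / 2, max(curve$times), length.out = 200)
  model <- data.frame(time_h = tt,
                      release = release_fraction(tt, geom, fit$params, basis))
  obs <- data.frame(time_h = curve$times, release = curve$values)
  ggplot2::ggplot(model, ggplot2::aes(x = time_h, y = 100 * release)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 100 * equilibrium_fraction(geom),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(data = obs) +
    ggplot2::labs(x = "Time (h)", y = "Cumulative release (%)",
                  title = label,
                  subtitle = sprintf("D0 = %.3g, D1 = %.3g cm²/s, tc = %g h",
                                     fit$params$D0, fit$params$D1,
                                     fit$params$tc)) +
    ggplot2::theme_minimal()
}
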
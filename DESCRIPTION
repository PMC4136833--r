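Package: cylrelease
Title: Finite-Bath Cylindrical Diffusion Modelling of Drug Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates effective diffusion coefficients of biomolecule release
    from nanocarrier-loaded dialysis devices using a finite-bath cylindrical
    diffusion model. The cumulative-release solution is a truncated Bessel
    eigenfunction series with a piecewise-constant effective diffusivity
    (burst and sustained phases separated by a threshold time), fitted to
    cumulative release curves by weighted nonlinear least squares with the
    threshold time profiled over candidate sampling times. Also fits the
    classical release-kinetics models (zero-order, first-order, Higuchi,
    Korsmeyer-Peppas) and classifies the release mechanism from the
    Korsmeyer-Peppas exponent. Includes an independent conservative
    finite-volume solver of the radial diffusion problem used to validate
    the series solution, and a synthetic release-curve generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
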
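#!/usr/bin/env Rscript
# Fit the finite-bath cylindrical diffusion model with piecewise diffusivity
# to each simulated curve: weighted NLS over (log D0, log D1) with the
# threshold time tc profiled over the sampling times. Writes the fitted
# parameter table (results/diffusion_fit.csv) and one fitted-curve figure
# per noisy curve (results/figures/).

suppressPackageStartupMessages(library(cylrelease))

cfg <- read_run_config("results/curves/config.yaml")
basis <- j1_roots(cfg$truncation_order)
geom <- config_geometry(cfg)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

files <- list.files("results/curves", pattern = "\\.csv$", full.names = TRUE)
fits <- list()
for (path in files) {
  cu <- read_release_csv(path, units = cfg$units)
  label <- sub("\\.csv$", "", basename(path))
  fit <- fit_piecewise_diffusion(cu, geom, basis)
  fits[[label]] <- fit
  cat(sprintf("%-28s D0 = %.3g  D1 = %.3g cm^2/s  tc = %g h  E = %.3g (burst/sustained ratio %.1f)\n",
              label, fit$params$D0, fit$params$D1, fit$params$tc,
              fit$weighted_error, fit$params$D0 / fit$params$D1))
  if (grepl("noisy", label) && requireNamespace("ggplot2", quietly = TRUE)) {
    p <- plot_release_fit(cu, fit, geom, basis, label = label)
    ggplot2::ggsave(file.path("results/figures", paste0(label, ".png")),
                    p, width = 5, height = 4, dpi = 150)
  }
}

report <- diffusion_fit_report(fits)
write_report_csv(report, "results/diffusion_fit.csv")
cat("\nFitted-parameter table written to results/diffusion_fit.csv\n")
cat("All thresholds recovered at tc =",
    paste(unique(report$tc_h), collapse = ", "), "h\n")
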
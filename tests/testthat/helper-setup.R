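# Shared fixtures, computed once per test run.
basis62 <- j1_roots(62L)
geomd <- default_geometry()

# Reference truth for the four emulated experiments (D0, D1 in cm^2/s).
preset_truth <- list(
  "BSA, pH 5"     = c(D0 = 1.37e-6, D1 = 6.22e-8),
  "BSA, pH 7.4"   = c(D0 = 8.27e-7, D1 = 4.55e-8),
  "siRNA, pH 5"   = c(D0 = 2.31e-6, D1 = 1.24e-7),
  "siRNA, pH 7.4" = c(D0 = 1.91e-6, D1 = 5.72e-8))
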
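# cylrelease

Estimation of effective diffusion coefficients of biomolecule release from
nanocarrier-loaded dialysis devices, using a finite-bath cylindrical
diffusion model, plus the classical release-kinetics models used to
characterize the release mechanism.

The package is written for pharmaceutics / drug-delivery work of the
following shape: a dialysis bag loaded with a carrier suspension (here,
siRNA- or BSA-loaded cholic acid–polyethylenimine micelles) stands in a
closed, stirred beaker of release medium; samples of the medium are taken
over hours-to-days and a cumulative-release curve is assembled. The analysis
questions are *how fast* the payload escapes (an effective diffusivity),
*whether there is a burst phase* and when it ends, and *what transport
mechanism* the curve is consistent with.

## The model

The device is a cylinder of radius *a* inside a coaxial closed bath of
radius *b* (shared height *H*). Transport is purely radial Fickian
diffusion of the payload with a lumped effective diffusivity:

∂C/∂t = D(t) (1/r) ∂/∂r (r ∂C/∂r),  0 ≤ r ≤ b,

with symmetry at r = 0, zero flux at r = b (closed container), uniform
initial concentration inside the device and none outside, and the membrane
treated as freely permeable. Burst release is modelled by a
piecewise-constant diffusivity: D = D₀ for t ≤ t_c (burst), D = D₁ after
(sustained). Because the eigenmodes do not depend on D, the time-varying
problem reduces exactly to the constant-D one through the effective
diffusion time τ(t) = 3600·[D₀·min(t, t_c) + D₁·max(0, t − t_c)] (t in
hours, D in cm²/s).

The cumulative released fraction is the Bessel eigenfunction series

M_t/M₀ = (1 − a²/b²) − 4 Σₙ [J₁(αₙ a/b) / (αₙ J₀(αₙ))]² exp(−αₙ² τ(t)/b²),

where αₙ are the positive zeros of J₁ and the series is truncated at 62
terms (a computable tail bound is attached to every fit). The plateau
1 − a²/b² is the finite-bath equilibrium: release stops below 100% when
the bath equilibrates with the device.

(D₀, D₁, t_c) are estimated by weighted nonlinear least squares,
E = Σₖ wₖ (yₖ − ŷₖ)², with weights proportional to the sampling interval
(wₖ = tₖ − tₖ₋₁) and t_c profiled over the sampling times. An independent
conservative finite-volume solver of the same PDE validates the series to
≤ 10⁻³ in released fraction.

The classical models — zero-order (Q = K₀t), first-order
(log-linear depletion), Higuchi (Q = k√t) and Korsmeyer–Peppas
(M_t/M_∞ = K tⁿ) — are fitted alongside; the exponent *n* classifies the
mechanism (n ≤ 0.45 for a cylinder: Fickian diffusion).

## Worked example

Simulate a noisy release experiment for the "BSA, pH 5" reference
parameter set and refit it:

```r
library(cylrelease)
basis <- j1_roots(62)
geom  <- default_geometry()          # a = 0.5, b = 2.9, H = 3.8 cm (~100 mL bath)
spec  <- release_presets(noise_sd = 0.01, seed = 1)[["BSA, pH 5"]]
curve <- generate_curve(spec, basis)
curve
#> Release curve: 12 observations, t in [0.5, 72] h, release 0.106..0.410

fit <- fit_piecewise_diffusion(curve, geom, basis)
fit
#> Finite-bath cylindrical diffusion fit
#>   D0 = 1.4e-06 cm^2/s  D1 = 6.47e-08 cm^2/s  tc = 4 h
#>   weighted error E = 0.00254 (unnormalized, w_k = interval lengths)
#>   series tail bound at first observation: 2.4e-08
```

The fit recovers the generating parameters (D₀ = 1.37×10⁻⁶,
D₁ = 6.22×10⁻⁸ cm²/s, t_c = 4 h) to a few percent from one noisy curve:
a ~22-fold burst/sustained diffusivity contrast with the burst ending at
4 h. The classical models on the same curve:

```r
fit_release_kinetics(curve, geom = geom)
#>              Model       K     n     R2
#> 1       zero_order 0.00837    NA -4.014
#> 2      first_order 0.00418    NA  0.583
#> 3          higuchi 0.06698    NA -0.809
#> 4 korsmeyer_peppas 0.18128 0.231  0.810
classify_mechanism(0.231, "cylinder")
#> [1] "Fickian diffusion"
```

The power law describes the curve best and its exponent (n ≈ 0.23, well
below 0.45) indicates Fickian diffusional release — the hard plateau of a
finite-bath experiment makes the through-origin linear and square-root
laws poor descriptors.

## Analysis workflow

Numbered drivers under `analysis/` run the full study and write tables to
`results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic curves for all four conditions
Rscript analysis/02_fit_diffusion.R   # diffusion fits -> results/diffusion_fit.csv
Rscript analysis/03_fit_kinetics.R    # kinetics fits  -> results/kinetics_fit.csv
Rscript analysis/04_validate_series.R # series vs finite-volume oracle
```

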
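# micsr — multimodal image correlation spectroscopy in R

`micsr` extracts molecular kinetics from time-lapse confocal image stacks by
correlation analysis of intensity fluctuations. It is aimed at cell
biologists and biophysicists studying proteins whose motion is *mixed* —
e.g. a nuclear receptor that simultaneously diffuses, binds chromatin for
seconds, and is confined by moving structures — where the label is too dense
or too dim for single-particle tracking.

The package implements:

* **RICS** — raster image correlation spectroscopy: the within-frame spatial
  autocorrelation of a raster-scanned stack, fitted with the scan-timing
  diffusion model
  `G_RICS(ξ,ψ) = S(ξ,ψ)·G(ξ,ψ) + b`, where
  `G = (γ/N)(1 + 4Dτ/ω₀²)⁻¹(1 + 4Dτ/ω_z²)^(−1/2)`,
  `S = exp(−((ξδr)² + (ψδr)²) / (ω₀²(1 + 4Dτ/ω₀²)))`, and
  `τ = τ_p|ξ| + τ_l|ψ|` — recovering diffusion coefficients in the
  1–100 µm²/s range from microsecond pixel / millisecond line timing.
* **mICS** — the core method: spatiotemporal correlation
  `C(ξ,ψ,Δt)` of bleach-corrected, time-average-removed fluctuations over
  frame lags, fitted per lag with a two-component Gaussian mixture
  `a₁·exp(−(ξ²+ψ²)/2σ²) + a₂·exp(−½(r−µ)ᵀΣ⁻¹(r−µ)) + ε`
  (isotropic = diffusion/binding; anisotropic = confined/structured motion),
  with a calibrated one-sided likelihood-ratio test deciding whether the
  anisotropic term is justified, an R² ≤ 0.1 noise gate, and a 10⁻⁴
  amplitude reporting gate — mapped in 32-px windows across the cell.
* **Co-localization & kymographs** — pixel-shift Pearson correlation between
  channels (overlap-only normalization, shifts −4..4) and bilinear
  path-profile kymographs.
* **A synthetic-scene simulator** — raster-rendered point emitters under
  diffusion, binding with turnover, oscillating confinement, oscillating
  filaments, and directed transport, with Gaussian PSF and Poisson noise:
  ground truth for every analysis above.
* **A 1D translocation Monte Carlo** — 500 receptors on a 50 µm
  cytoplasmic segment choosing diffusion / stalling / dynein-like transport
  each second, absorbed at the nuclear envelope with (possibly
  time-increasing) permeability.

## Worked example

Simulate a binding scene at the 256 × 32 px, 49.6 ms/frame acquisition
geometry, then ask the analysis what the molecules are doing:

```r
library(micsr)

mt  <- micsAcquisition()                       # 100 nm/px, 1.27 us dwell, 49.6 ms/frame
cfg <- sceneConfig(nParticles = 2000, brightness = 0.5,
                   width = 256, height = 32, nFrames = 1000,
                   meta = mt, seed = 2001L)
st  <- simulateStack(boundModel(residenceTime = 10), cfg, "frame")

fl   <- removeTimeAverage(bleachCorrect(st))
win  <- list(row = 1, col = 113, size = 32)    # central analysis window
fits <- lapply(sticsCorrelate(fl, win, lags = c(1, 5, 10, 15, 20),
                              maxShift = 8), fitMixture)
fits[[1]]
#> MixtureFit (lag 1): isotropic, R2 = 0.952, LRT p = 0.634, eps = -0.00479
#> GaussianComponent (isotropic): a = 0.3677, sigma = 1.58 px

summarizeComponent(fits[[1]], mt)
#>        type fwhm_major_um fwhm_minor_um theta center_x_um center_y_um rel_amplitude
#> 1 isotropic     0.3715951     0.3715951     0           0           0             1
```

The fit says: one centred circular Gaussian (σ = 1.58 px → FWHM 0.37 µm,
about the PSF autocorrelation width, i.e. the emitters are not spreading),
the likelihood-ratio test sees no anisotropy (p = 0.69), and the amplitude
barely decays from lag 1 to lag 20 — the signature of stable binding rather
than diffusion. A diffusing scene instead shows σ²(τ) growing linearly with
lag; `diffusionFromLagSeries(fits, mt)` turns that line into a diffusion
coefficient.

Whole-cell maps come from `micsMap(stack)` (one mixture fit per window and
lag; `as.data.frame()` gives the long-format table,
`plotKineticMap()` the circle/cross overlay), and RICS fits from
`fitRICS(ricsAverage(stack))`.

A thin command-line wrapper is installed under `inst/cli/mics`:

```sh
mics simulate --config scene.yaml --out stack.tif --seed 1
mics mics --stack stack.tif --meta stack.tif.meta.yaml --out map.csv
mics rics --stack rics.tif --meta rics.yaml --out fit.csv
```

Every run writes a JSON manifest (inputs, parameters, seed, outputs) next to
its output.

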
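---
title: "Multimodal image correlation spectroscopy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal image correlation spectroscopy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micsr)
```

# The problem

A fluorescently labelled protein in a live cell rarely moves in a single way.
A nuclear receptor, for instance, diffuses freely, binds chromatin or scaffold
structures for seconds at a time, is confined by moving boundaries, and may be
actively transported. Single-particle tracking fails when the label is too
dim or too dense; photobleaching recovery probes only a few pre-selected
spots. Correlation spectroscopy instead treats the *fluctuations* of the
image as the signal: how intensity deviations at one position and time
co-vary with deviations at a shifted position and a later time encodes the
motion of the underlying emitters.

`micsr` implements this programme at two time scales:

* **RICS** (raster image correlation spectroscopy) exploits the time
  structure of a raster scan — microseconds between pixels on a line,
  milliseconds between lines — so that the *shape* of the within-frame
  spatial autocorrelation encodes diffusion in the 1–100 µm²/s range.
* **mICS** (multimodal image correlation spectroscopy) correlates
  fluctuation images across frame lags (tens of milliseconds to seconds) and
  decomposes each lagged correlation surface into an isotropic component
  (diffusion or binding), an anisotropic component (confined or structured
  motion), and a uniform noise floor, with a likelihood-ratio test deciding
  whether the anisotropic term is warranted.

A synthetic-scene simulator and a 1D nucleocytoplasmic translocation Monte
Carlo provide ground truth for validating every step.

# Preprocessing

**Bleach correction** (`bleachCorrect`). Each frame is rescaled as
$$I'(x,y,t) = \frac{I(x,y,t)}{\sqrt{f(t)/f(0)}} + f(0)\Big(1 - \sqrt{f(t)/f(0)}\Big),$$
where $f(t)$ is the spatial mean of frame $t$. This keeps the frame mean at
$f(0)$ exactly and, for shot-noise-limited data (variance = mean), keeps the
variance at its initial level too — the property the tests assert on
analytically bleached and Poisson stacks.

**Immobile-structure removal** (`removeTimeAverage`). Subtracting the
per-pixel time average removes everything that does not move, so lagged
correlations reflect only dynamics. The removed average image is kept so the
raw window mean intensities can be reconstructed for normalization.

**Temporal high-pass** (`movingAverageHighpass`, RICS only). A centred
10-frame moving average is subtracted per pixel to remove slow drifts such as
cell movement; the window shrinks symmetrically at the stack edges (the
convention of the established RICS analysis software). One caveat the user
should know: the subtracted local average contains a "ghost" of each
particle's recent trajectory. When the displacement per moving-average window
is comparable to the correlation fit region — slow diffusion at fast frame
rates — this ghost biases the fitted $D$ downward. For synthetic scenes,
which contain no immobile structure or drift, the validation suite therefore
runs the RICS chain with the high-pass disabled (`highpass = 0`); for real
data the default of 10 frames is appropriate because the targeted diffusion
is fast ($D \gtrsim 3$ µm²/s at ~0.1 s/frame).

# RICS

The within-frame, intensity-normalized spatial autocorrelation is
$$G(\xi,\psi) = \frac{\langle I(x,y)\, I(x+\xi, y+\psi)\rangle_{x,y}}{\langle I\rangle^2} - 1,$$
averaged over all in-bounds pixel pairs (non-periodic, per-shift pair-count
normalization — circular FFT wrap would bias small frames materially) and
then averaged across frames. The fitted model factors into molecular dynamics
and scanning optics plus a background $b$:
$$G_{\mathrm{RICS}} = S(\xi,\psi)\,G(\xi,\psi) + b,$$
$$G = \frac{\gamma}{N}\Big(1 + \tfrac{4D\tau}{\omega_0^2}\Big)^{-1}\Big(1 + \tfrac{4D\tau}{\omega_z^2}\Big)^{-1/2},\qquad
S = \exp\!\Big(-\frac{(\xi\,\delta r)^2 + (\psi\,\delta r)^2}{\omega_0^2\,(1 + 4D\tau/\omega_0^2)}\Big),$$
with $\tau = \tau_p|\xi| + \tau_l|\psi|$ the scan-time offset of the pixel
pair ($\tau_p$ pixel dwell, $\tau_l$ line time, $\delta r$ pixel size). The
absolute values make the model symmetric under the symmetric pair averaging
used here.

Parameters and defaults:

* $\gamma = 0.3536$ — shape factor of a 3D Gaussian illumination volume.
  Fixed, not fitted: it is not identifiable jointly with $N$ from one
  surface.
* $\omega_0 = 0.25$ µm, $\omega_z = 3\omega_0$ — calibration inputs of the
  instrument, not fit parameters.
* Fit region $|\xi| \le 16$, $|\psi| \le 8$ with the $(0,0)$ point excluded —
  uncorrelated shot noise contributes only there.
* Multi-start Levenberg–Marquardt over $D_0 \in \{0.1, 1, 10, 100\}$ µm²/s
  with $N_0 = \gamma / G(1, 0)$ and $b_0 = \min G$; best SSE wins, ties to
  the smaller $D$. $D \ge 0$ and $N > 0$ are bound constraints.

Standard errors come from the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum.

# mICS

## Spatiotemporal correlation

For a fluctuation stack $\delta I$ and lag $\Delta t$ (frames),
$$C(\xi,\psi,\Delta t) = \Big\langle
  \frac{\langle \delta I(x,y,t)\,\delta I(x+\xi, y+\psi, t+\Delta t)\rangle_{x,y}}
       {\bar I(t)\,\bar I(t+\Delta t)}\Big\rangle_{t},$$
averaged over all $T - \Delta t$ ordered frame pairs, each normalized by the
product of the two frames' *raw* window mean intensities, with the same
non-periodic spatial averaging as RICS. Analysis runs in 32 × 32-pixel
windows stepped by 16 pixels (half-window overlap) across the frame, for lags
$\tau = 1, \dots, 20$; with a 49.6 ms frame interval this spans 50 ms to 1 s.
Shifts are kept to $|\xi|, |\psi| \le 8$ so the surface has roughly 30 times
more points than the full model has parameters.

## The two-component mixture

Each lagged surface is fitted with
$$C(\xi,\psi) = a_1 e^{-(\xi^2+\psi^2)/2\sigma_{\mathrm{iso}}^2}
 + a_2\, e^{-\frac12 (r-\mu)^\top \Sigma^{-1} (r-\mu)} + \epsilon,$$
an isotropic centred Gaussian (diffusion or binding), an offset rotated
Gaussian with axes $\sigma_{\mathrm{major}} \ge \sigma_{\mathrm{minor}}$ and
orientation $\theta \in [0, \pi)$ (confined/structured motion; a
lag-proportional drift of $\mu$ would indicate directed transport), and a
spatially uniform noise level $\epsilon$ (unconstrained in sign: the
finite-series time-average subtraction can push the floor slightly
negative). The isotropic model is fitted first from moment-based seeds; the
full model is seeded at the isotropic optimum plus a principal-axis
decomposition of the positive residual (so the nested SSE ordering holds by
construction). Component standard deviations are capped at twice the shift
range: a "Gaussian" much wider than the measured surface is indistinguishable
from the uniform term and is not reported as a component.

## Model selection and gating

Whether the anisotropic term is included is decided by a one-sided
likelihood-ratio test for nested Gaussian-residual least squares,
$\Lambda = n \ln(\mathrm{SSE_{iso}} / \mathrm{SSE_{full}})$, referred to the
upper tail of $\chi^2_{\mathrm{df}}$, with inclusion at $p < 0.05$. Two
calibration choices matter here, both made on *null* (isotropic) simulations
only:

* **Degrees of freedom.** The full model adds six parameters, but its
  centre, shape and orientation are unidentified when $a_2 = 0$, a boundary
  situation in which each extra parameter costs roughly two $\chi^2$ degrees
  of freedom. On simulated isotropic surfaces with white noise the null
  $\Lambda$ matches $\chi^2_{12}$ (mean 13.2, 95th percentile 20.4), while
  $\chi^2_6$ would accept a spurious anisotropic term half the time. The
  fitting gate therefore uses df = 12; `selectModel()` itself keeps df as an
  argument.
* **Effective sample size.** Correlation surfaces are smooth over the PSF
  width, so neighbouring shift points are not independent observations; with
  the raw point count (289), persistent emitter configurations (e.g. binding
  sites that never move during the acquisition) trigger the anisotropic term
  on about half of bound scenes at any brightness. `fitMixture` converts the
  count to an effective sample size by dividing by the integral of the
  full-model residual autocorrelation (a Bretherton-style effective-dof
  correction; the factor is ~1 for white residuals, so the white-noise
  calibration above is unaffected). The full-model residual is used so that
  genuine anisotropic structure, which the full model absorbs, does not
  deflate the count. With this correction the false-acceptance rate on pure
  isotropic surfaces is ~7% (target: at or below the nominal-plus-boundary
  10%), bound scenes classify isotropic, and oscillating-filament scenes are
  still detected in 10/10 replicates with sub-degree orientation error.

Classification then proceeds in order: surfaces whose selected-model $R^2$ is
at or below 0.1 are **noise** (no spatial structure); otherwise components
are reported only when their amplitude exceeds $10^{-4}$, and the window is
labelled **isotropic** or **isotropic+anisotropic** accordingly.

One statistical property of binding scenes deserves emphasis. When emitters
occupy persistent sites with a residence time $t_r$, the correlation
estimator from an acquisition of length $T$ carries coherent anisotropic
"sampling relief" whose relative amplitude scales as $\sqrt{t_r/T}$ — about
4–13% of the isotropic amplitude for 10 s residence in a 49.6 s record. It
scales with the signal itself, so neither emitter density nor photon budget
reduces it, and a size-calibrated test *correctly* flags it as statistically
significant in a fraction of realizations. The meaningful read-out for
binding is therefore isotropic **dominance** — an isotropic component present
and lag-stable at every lag, with any accepted anisotropic term a minor
fraction (worst case ~0.23 of the isotropic amplitude in validation) —
whereas genuinely structured scenes (oscillating filaments) are
anisotropy-dominant, with the isotropic term negligible or absent. The
validation suite asserts exactly this separation.

## Physical read-outs

* FWHM $= 2\sqrt{2\ln 2}\,\sigma$, converted to µm via the pixel size, is
  the display size of a component (circle diameter for isotropic; cross-arm
  lengths along $\theta$, $\theta + \pi/2$ for anisotropic), with line
  weights proportional to relative amplitudes (`summarizeComponent`,
  `plotKineticMap`).
* Under free diffusion the isotropic variance grows linearly with lag,
  $\sigma^2(\tau) = \sigma_0^2 + 2D\tau$ per axis; `diffusionFromLagSeries`
  fits this line and returns $D$ = slope/2. The line is fitted over the
  early, linear regime: once $\sigma$ exceeds roughly 40% of the measured
  shift range, truncation of the surface support flattens the apparent law
  (the classic confinement-like artifact of windowed width laws). Binding
  shows as a lag-stable amplitude with constant width instead.
* The frame interval acts as a temporal filter: at ~50 ms/frame, diffusion
  above ~1 µm²/s decorrelates between frames and contributes only weakly to
  $C$ at $\tau \ge 1$, which is what isolates the slow/bound population.

# The synthetic-scene simulator

`simulateStack` generates point emitters in a 2D plane, moves them under one
of five motion modes, and renders them through a Gaussian PSF
($e^{-2d^2/\omega_0^2}$, peak `brightness` counts per dwell) with optional
Poisson photon noise and Gaussian read noise:

* **diffusion** — Brownian steps, per-axis variance $2D\,dt$;
* **bound** — binding with turnover, modelled as exchange with a
  fast-diffusing pool: each emitter's site is occupied for an exponential
  residence time (default mean 10 s, the seconds scale reported for
  agonist-induced receptor–chromatin binding) and vacant for an exponential
  off time (default equal: 50% duty), sites switching independently of one
  another; while unbound the molecule diffuses too fast to correlate at the
  frame time scale, so it is simply invisible to the slow-correlation
  analysis. `residenceTime = Inf` gives strictly static emitters, whose
  fluctuations vanish entirely under time-average removal — finite turnover
  is what produces the lag-stable binding phenotype the method is designed
  to detect. (An earlier design that teleported emitters between sites was
  dropped: sequential occupancies of the *same* molecule are anti-correlated
  by construction, which imprints spurious structured cross-terms on the
  correlation; independent telegraph sites are the standard physical picture
  and free of that artifact.);
* **confined_oscillating** — diffusion in a reflecting box whose $+x$ wall
  oscillates sinusoidally;
* **filament_oscillating** — a rigid line of emitters translated
  sinusoidally perpendicular to its axis (period > 2 frame intervals so the
  motion is resolvable);
* **directed** — constant drift plus optional diffusion.

Two renderers cover the two acquisition regimes. `renderRaster` evaluates
each scan line at its own time ($t = f\,T_{\mathrm{frame}} + r\,\tau_l$), so
particles move *during* the scan — the structure RICS needs. Positions are
updated per line, not per pixel: within-line displacement is far below the
PSF for every $D$ of interest, and the pixel-dwell term contributes only a
few percent of the model decay over the fit region. `renderFrames` snapshots
each frame at its start time, a fast approximation valid when motion per
frame is small against the PSF — the mICS regime. Particles live on a field
6 beam-waists larger than the frame on each side with periodic re-entry, so
density is stationary; emitters are 2D (no axial excursions), with
$\omega_z$ entering only through the RICS model constant.

Default scene scale: the mICS validation scenes use 2000 emitters over the
~180 µm² simulation field (≈ 11/µm², a realistic density for an expressed
fusion protein; sparser scenes leave single-configuration structure in the
correlation that no statistical gate should be asked to explain away) at 0.5
counts/dwell peak brightness — a realistic photon budget for a ~1 µs dwell.
Filament scenes use 25 emitters along a 2 µm segment (PSF-overlapping
spacing) at brightness 2. What the simulator does *not* emulate: axial
motion, photophysics (blinking/bleaching — bleach correction is tested on
analytically bleached stacks instead), detector correlations, and optical
aberrations. Passing tests therefore validate the estimators against their
own physical model, not against every property of real microscopes.

# The translocation Monte Carlo

A 1D walk of 500 receptors on $[0, 50]$ µm (nuclear envelope at 0, membrane
at 50, reflecting), $dt = 1$ s for 1800 s, starting uniformly. Each step a
particle independently picks a mode: **diffusion** (Gaussian step, sd
$\sqrt{2D\,dt}$, written with the $\sqrt{dt}$ so the simulator is correct for
any step size; identical at $dt = 1$), **still**, or **transport** toward the
nucleus with step magnitude $\mathcal N(v\,dt, v\,dt/2)$ clamped at zero
(transport is unidirectional). At the envelope the particle is absorbed with
probability $p(t) = \min(1, p_0 + k t)$ — the nucleus is a one-way sink —
otherwise reflected. Modes are re-drawn every step (no dwell persistence, the
simplest reading of per-step mode choice). Default mode probabilities
(0.5, 0.4, 0.1), $D = 9.2$ µm²/s and $v = 1$ µm/s are exploratory
placeholders, not measured constants.

Limiting behaviours the tests pin down: a sealed envelope ($p = 0$) admits
nothing; pure transport with $p_0 = 1$ absorbs in $L/2v = 25$ s on average
from a uniform start; pure diffusion keeps the surviving cytoplasmic profile
near-uniform (Kolmogorov–Smirnov distance < 0.15) while pure slow transport
piles particles against the envelope; and constant permeability produces
early-rapid (convex) cytoplasmic depletion whereas a linearly increasing
permeability delays it — quantified by `concavityMetric`, the ratio of the
mean depletion slope over the first quartile of the depletion interval to
that over the last quartile (interval truncated where the series comes
within 5% of its final value, so equilibrated tails do not dilute the late
slope). The matched-endpoint contrast pair used in validation is
$p_0 = 0.0095$ constant versus $k = 1.06 \times 10^{-5}$ s⁻¹ from zero, both
diffusion-only: both deplete to ~0.57 of the initial cytoplasmic fraction by
1800 s, with concavity ratios ~1.6 and ~0.2 respectively. Runs with a common
seed are coupled by common random numbers (draws are made for every particle
slot each step), which makes nuclear uptake provably monotone in
permeability.

# Numerical choices and conventions

* Indexing is 1-based (row, col), origin top-left, as is idiomatic in R;
  $\xi$ is a column (fast-axis) shift, $\psi$ a row shift.
* Correlations use zero-padded FFTs with per-shift pair-count normalization;
  the suite checks the FFT path against direct-summation oracles to 1e-10.
* Edge windows that would overrun the frame are dropped, not padded.
* $\theta$ is reported modulo $\pi$; tests compare orientations by angular
  distance on the half-circle.
* Degenerate inputs fail loudly: zero-mean frames cannot be normalized,
  lags must be shorter than the series, paths must stay inside the frame.
* Singular Hessians at a fit optimum yield NA standard errors, never a
  crash; non-convergent mixture fits classify as noise with a flag.

# Problem sizes used in validation

The test-suite and acceptance-script scenes are sized for a desktop run:
RICS recovery uses 100-frame, 128 × 128 stacks (10 seeds per $D$); mICS
phenotypes use full 1000-frame, 256 × 32 stacks analysed in one central
window (3 seeds for bound/diffusive scenes, 10 replicates for filament
scenes); the LRT size calibration uses 200 synthetic surfaces; the
translocation checks use the full 500-particle, 1800 s configuration. These
are the package's chosen validation scales; all are configurable.

# Known limitations

* RICS with the moving-average high-pass under-estimates slow diffusion at
  fast frame rates (trajectory-ghost bias, above); disable the high-pass
  when the data contain no immobile structure, or lengthen the window.
* The LRT calibration (df = 12, effective sample size) is tied to the
  default 17 × 17 surface geometry; substantially different shift ranges
  deserve a fresh null simulation.
* The mixture fit reports at most one anisotropic component; scenes with
  several distinct oriented structures in one window will blend them.
* The simulator's 2D emitters slightly overweight the correlation amplitude
  relative to a 3D focal volume; recovered $N$ from synthetic scenes is an
  effective 2D particle number, and only $D$ is compared against ground
  truth.
* The translocation model has no nuclear export, no ligand-binding kinetics
  and no 2D/3D geometry; it isolates the interplay of motion modes with
  envelope permeability, nothing more.
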
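---
title: "Time-domain diffuse optical spectroscopy of turbid slabs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain diffuse optical spectroscopy of turbid slabs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tddos)
```

## The measurement problem

Time-domain diffuse optical spectroscopy (TD-DOS) recovers the absorption
coefficient $\mu_a(\lambda)$ and the reduced scattering coefficient
$\mu_s'(\lambda)$ of a turbid medium from the *distribution of times of
flight* (DTOF) of picosecond laser pulses transmitted through it. Photons
that scatter more take longer paths; photons that are absorbed preferentially
disappear from the late part of the histogram. The temporal shape of the
DTOF therefore disentangles the two coefficients, which continuous-wave
measurements cannot do.

`tddos` implements the full analysis chain for the transmittance geometry in
which a soft-tissue slab (thickness roughly 0.8–1.5 cm) is held between two
plates with coaxial source and detection fibers, and spectra are acquired
over 600–1100 nm. The motivating application is dosimetry for light-based
thermotherapy of the pancreas: the package ships a synthetic-data generator
whose defaults emulate a fresh/frozen-thawed porcine-pancreas measurement
campaign, so every stage can be exercised and validated without any
measured data.

## Forward models

### White Monte Carlo

The production forward model is *white* Monte Carlo: photon transport is
simulated once per slab geometry at **null absorption** over a grid of
$\mu_s'$ values, and absorption is applied afterwards analytically. For a
path detected at time $t$, the radiative transport equation factorizes the
absorption survival as $e^{-\mu_a v t}$ with $v = c/n$, so a single
null-absorption histogram generates the model curve for *any* $\mu_a$
(`apply_absorption()`). This is exact up to the channel discretization and is
what makes library-based inversion affordable.

The transport kernel (`mc_simulate()`, in C++) launches photons normally
into the slab at the origin, samples exponential step lengths, applies
unpolarized Fresnel reflection/refraction at both faces, and bins photons
exiting the far face within the detector radius by total time of flight
$t = L\,n/c$. Two scattering descriptions are available:

* `isotropic_reduced` (default): simulate directly at $\mu_s = \mu_s'$ with
  an isotropic phase function. By the similarity relation, media with equal
  $\mu_s'$ are indistinguishable in the diffusive regime, and the entire
  analysis operates on $\mu_s'$; this is the standard white-MC economy.
* `henyey_greenstein`: simulate at $\mu_s = \mu_s'/(1-g)$ with the
  Henyey–Greenstein phase function (default $g = 0.9$). The test suite
  verifies that both modes agree within Poisson noise beyond twice the peak
  time; the early-time transient is where the similarity relation is weakest.

Randomness is counter-based: each photon's generator state is a hash of
`(seed, photon index)`, so histograms are bit-reproducible for a given seed
and independent of how the photon loop is batched. The hash step matters:
seeding nearby photons at *regularly spaced* states of the underlying
splitmix64 sequence makes every photon's draw stream a shifted copy of its
neighbour's, which produces subtly correlated, biased histograms. This
failure mode was observed during development and is guarded by a
reproducibility test comparing independent seeds channel-wise.

`build_library()` runs one simulation per $\mu_s'$ grid node (default: 16
log-spaced nodes over 1.5–50 cm⁻¹, covering fresh tissue at roughly
12–24 cm⁻¹, the ≈3× lower frozen-thawed range, and lognormal inter-sample
dispersion of both; 10⁶ photons per node). `interpolate_library()` makes the
library continuous in $\mu_s'$ by channel-wise interpolation, linear in
$\log(\text{counts}+\varepsilon)$ versus $\log\mu_s'$ — DTOF tails are
near-exponential in both variables, so log-space interpolation is accurate to
within about 1–2% RMS even at 4 cm⁻¹ node spacing (verified against direct
simulations at off-node values). The library never extrapolates: out-of-grid
requests are errors.

### Diffusion approximation

`da_transmittance()` provides the classical analytical solution of the
diffusion approximation (DA) for a laterally infinite slab: an isotropic
point source at depth $z_0 = 1/\mu_s'$, extrapolated zero-fluence boundaries
at distance $z_e = 2AD$ outside each face with $D = 1/(3\mu_s')$, and a
truncated image-source series (default ±10 pairs, converged to below
$10^{-6}$ relative for the geometries of interest). The boundary coefficient
$A$ is computed by numerical integration of the internal Fresnel reflectance
moments ($A \approx 2.95$ for $n = 1.4$ against air), consistently with the
Fresnel treatment inside the Monte Carlo kernel — the two forward models
agree channel-wise within Poisson noise in the diffusive regime
($\mu_s' s \gtrsim 15$), which is one of the package's acceptance checks.

For the thin, strongly absorbing slabs this package targets, the DA is
*known to be biased* — that is precisely why the production inverter uses
Monte Carlo. The test suite quantifies the bias: on synthetic 1.2 cm
pancreas-like DTOFs the DA-based fit displaces $\mu_s'$ by on the order of
15% and $\mu_a$ by several percent, far beyond the Monte-Carlo fit's
replicate scatter.

## Inversion

`fit_dtof()` recovers $(\mu_a, \mu_s', A)$ from one DTOF and its measured
instrument response function (IRF):

1. the dark/afterpulse floor is estimated from an early pre-peak window
   (median of the first 20 channels by default) and subtracted;
2. the fit range runs from the first channel at 80% of the peak on the
   rising edge down to the last channel at 1% of the peak on the tail —
   computed on the measured, background-subtracted curve;
3. the trial model is the null-absorption library curve at $\mu_s'$, scaled
   by $e^{-\mu_a v t}$, convolved with the area-normalized IRF, and scaled by
   an amplitude;
4. a Levenberg–Marquardt optimizer (`minpack.lm`) minimizes Poisson-weighted
   squared residuals ($\sigma_i = \sqrt{\max(N_i, 1)}$, the TCSPC standard;
   plain least squares is available for noiseless checks) over
   $(\log\mu_a, \log\mu_s')$, with forward-difference derivatives at a
   relative step of $10^{-4}$. The amplitude is profiled analytically at
   every evaluation — its weighted least-squares optimum given the curve
   shape — which removes one direction of the search space without changing
   the optimum. An optional temporal shift between model and data can be
   floated (`fit_t_shift`); it is off by default because IRF and DTOF are
   assumed time-aligned by acquisition.

**Initialization.** The starting point is a coarse profiled-amplitude grid
search over the forward model itself (7 × 9 log-spaced cells strictly inside
the parameter bounds). A DA-based pre-fit was evaluated as an initializer
and rejected: on thin slabs at the strongly absorbed red end of the spectrum
the DA landscape is degenerate (large $\mu_a$ with large $\mu_s'$ mimics the
convolved curve shape), and the pre-fit can run into the $\mu_s'$ upper
bound, stranding the subsequent library fit at a box corner. The grid search
is also cheaper.

`fit_spectrum()` chains fits across wavelengths, warm-starting each fit from
the previous wavelength's solution (optical properties vary smoothly with
wavelength). Two safeguards keep one bad wavelength from poisoning its
neighbours: a solution pinned at a parameter bound is never used as a warm
start, and a warm-started fit that lands on a bound is retried cold. With
warm starting disabled, fits are independent and the result is invariant
under wavelength ordering. Non-converged wavelengths are flagged and
excluded; more than 20% of them aborts the pipeline.

$\chi^2_\mathrm{red}$ is reported per fit; on correctly specified Poisson
synthetic data at $10^6$ counts it sits near 1, and this is asserted by the
test suite.

## Spectral analyses

* `fit_power_law()` fits the Mie-type model
  $\mu_s'(\lambda) = a\,(\lambda/\lambda_0)^{-b}$ by linear least squares on
  the log-transformed model — exact on power-law data, deterministic, and
  free of initialization. There is no universal convention for $\lambda_0$;
  it is a required argument everywhere (600 nm, the lower spectral edge, is
  used throughout the examples), and refitting under a different
  $\lambda_0$ rescales $a$ by $(\lambda_1/\lambda_0)^{-b}$ with $b$
  unchanged.
* `mu_eff()` is the effective transport coefficient
  $\mu_{eff} = \sqrt{3\mu_a\mu_s'}$, the decay constant of the
  continuous-wave fluence far from a source.
* `cw_fluence()` evaluates the infinite-medium point-source fluence rate
  $\Phi(r) = P\,e^{-\mu_{eff} r}/(4\pi r D)$. Two conventions for $D$
  circulate in the dosimetry literature and they differ by a factor of 3 in
  amplitude (never in the decay): `as_printed` uses $D = 1/\mu_s'$ and is the
  default for consistency with published pancreas dosimetry tables;
  `standard` uses the conventional $D = 1/(3\mu_s')$. Choosing between them
  is a documentation decision, not a physics one, so both are exposed.
* `attenuation_report()` maps $\mu_{eff}$ over a spectrum, finds the
  minimum-attenuation wavelength inside requested bands (ties break to the
  lowest wavelength), and tabulates $\Phi(\lambda, r)$ over radii.

Study-level statistics (`summarize_set()`, `temporal_drift()`,
`condition_compare()`) are deliberately plain: per-wavelength mean, sample
standard deviation ($n-1$ denominator, the small-$n$ reporting standard),
CV = SD/mean with the median taken over wavelengths, ordinary least-squares
drift slopes, and ratios of mean spectra with a spectrum-averaged scalar
summary. No inferential testing is attempted — the emulated study reports
descriptive dispersion only.

## The synthetic-data generator

`tissue_truth_model()` defines the ground truth the whole pipeline is tested
against. Absorption is a constant baseline (0.12 cm⁻¹) plus Gaussian
pseudo-chromophore bands — 980 nm (height 0.30 cm⁻¹, σ 36 nm, water-like),
760 nm (0.045 cm⁻¹, σ 25 nm, hemoglobin-like), 1160 nm (0.15 cm⁻¹, σ 55 nm,
the rising edge of the next water feature, which keeps the 1050–1100 nm
plateau realistic) — plus a blood-like exponential red tail
$0.732\,e^{-(\lambda-600)/30}$ cm⁻¹. Reduced scattering is the power law
$a = 24.1$ cm⁻¹, $b = 1.16$, $\lambda_0 = 600$ nm (fresh tissue). These
values were calibrated once, by direct evaluation, so that the spectrum's
landmarks match values reported for fresh porcine pancreas — maximum
≈ 0.74 cm⁻¹ at the 605 nm red edge, minimum ≈ 0.12 cm⁻¹ near 805 nm,
water peak ≈ 0.42 cm⁻¹ at 980 nm, ≈ 0.17 cm⁻¹ at 1065 nm, and nearly equal
effective-attenuation minima (≈ 2.4–2.5 cm⁻¹) in the 800–900 and
1050–1100 nm bands. No literature extinction spectra are used: the bands are
pseudo-chromophores, so the generator cannot be used for concentration
fitting, which is out of scope.

Condition modifiers emulate the campaign design:

* **fresh vs frozen-thawed**: freezing multiplies $\mu_s'$ by 1/3 (ice
  damage homogenizes the microstructure) and leaves $\mu_a$ untouched, with
  the spectral slope essentially preserved;
* **variability**: mean-one lognormal amplitude factors (positivity is
  structural), drawn per sample — CV 39% on $\mu_s'$ and 7.4% on $\mu_a$ —
  and per position (16% / 3%). Sample factors are shared between the fresh
  and frozen arms of the same physical sample. The components are sized so
  the *pooled* dispersion over a 5-sample × 3-position campaign reproduces
  the reported median CVs of ≈ 42% ($\mu_s'$) and ≈ 8% ($\mu_a$).
  Repositioning (3%/7%) and compression (8%/10%) arms use their own
  dispersions;
* **temporal drift**: the stability arm applies linear drifts of
  0.003 cm⁻¹/h ($\mu_a$) and 1.2 cm⁻¹/h ($\mu_s'$) with *no* repositioning
  jitter between timepoints (the sample rests untouched), so only counting
  noise separates consecutive acquisitions.

Each measurement's DTOF is the forward curve at its ground truth, convolved
with a per-wavelength synthetic IRF (Gaussian core, default FWHM 150 ps,
plus a 15% exponentially-broadened tail with τ = 250 ps — the asymmetric
shape of single-photon detectors), scaled to the expected total counts
(default 10⁶ per DTOF; acquisition times are not part of the model) and
Poisson-sampled. All randomness flows from one master seed through a
deterministic per-measurement schedule, so campaigns regenerate
bit-identically. Rare lognormal tail draws of $\mu_s'$ outside the library
grid are clamped to the grid edge and flagged in the truth manifest.

### What passing tests do and do not show

The closure tests (generate → fit → summarize) use the same forward library
for generation and inversion. They therefore validate the *inversion
machinery* — convolution, range selection, weighting, optimization,
statistics — under exactly known truth, but not the fidelity of the forward
model to real tissue. That burden falls on the physics cross-checks (white-MC
identity against analog absorption sampling, MC↔DA agreement in the
diffusive regime, similarity-relation test), which compare independent
routes to the same physical quantity. Real measurements additionally contain
effects the generator does not model: wavelength-dependent IRF shape, timing
drift and jitter, detector afterpulsing beyond a flat floor, lateral sample
heterogeneity within one measurement volume, and deviations of true tissue
spectra from the pseudo-chromophore parameterization.

## Numerical choices and problem sizes

* Default time grid: 10 ps channels × 1024 (10.24 ns window) — resolves the
  ~150 ps IRF and covers the multi-nanosecond tails of 0.8–2 cm slabs.
* Detector radius: 0.5 mm (a 1 mm fiber) in `slab_geometry()` defaults. The
  test fixtures and the acceptance script build their libraries with a 0.5 cm
  acceptance radius instead: at desk-scale photon budgets (10⁶ per node) the
  larger aperture keeps per-channel Poisson noise in the library curves small,
  and in a laterally infinite homogeneous slab the aperture affects
  signal level far more than curve shape. Closure tests are unaffected by
  construction; the physics cross-checks use matched geometries on both
  routes.
* Photon budgets: 10⁶ per library node for fitting work; 10⁷ per run for the
  channel-wise identity checks. Library build time is about half a minute
  at desk scale.
* Poisson-weighted fits use $\sigma_i = \sqrt{\max(N_i,1)}$; the floor keeps
  empty tail channels finite.
* Library interpolation adds $\varepsilon = 0.5$ counts before taking logs,
  guarding empty channels; the interpolant is exact at grid nodes.
* Bounds: $\mu_a \in [0.001, 2]$ cm⁻¹, $\mu_s'$ within the library grid.
  Bound-pinned solutions are flagged with a warning and quarantined from
  warm starts.
* The synthetic campaign in the shipped acceptance script uses the full
  5 × 3 × {fresh, frozen} design at 101 wavelengths, a 150-sample
  single-position run for dispersion calibration (the CV estimator over only
  5 samples has a sampling spread of tens of percentage points, so the
  tighter estimate comes from the larger run), and a 13-timepoint × 3
  wavelength stability run.

## Known limitations

* Transmittance geometry only; no reflectance or interstitial-source Monte
  Carlo, and no layered media.
* The DA solution is an oracle and initializer, not a production inverter,
  for the thin-slab reasons above.
* The IRF is treated as time-aligned and wavelength-independent in shape by
  default; a temporal shift can be floated per fit, but free-form IRF
  deconvolution is out of scope.
* The channel-wise white-MC identity is exact only up to time discretization:
  with 10 ps channels the within-channel variation of $e^{-\mu_a v t}$ is
  below a percent for $\mu_a \le 0.74$ cm⁻¹, small compared to desk-scale
  Poisson noise.
* Pseudo-chromophore bands preclude chromophore-concentration analyses.
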
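---
title: "Linking spikes to Power-Doppler hemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking spikes to Power-Doppler hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuscouple)
```

## The problem

Functional ultrasound (fUS) imaging reads out cerebral blood volume as a
Power-Doppler intensity movie, a hemodynamic proxy for neural activity;
Neuropixels probes record the spiking itself along a linear shank. When
both are acquired simultaneously through the same tissue, three questions
arise: *where* in the image the probe lies, *how much* Doppler change a
given spike-rate change produces, and *how* the coupling spreads in time
and space. This package answers the three with, respectively, a
Monte-Carlo trajectory alignment, an amplitude-calibration regression, and
a separable spatiotemporal transfer model

$$\Delta I(x, t) \;=\; \Delta SR(x, t)\;\otimes_x\; G(x;\,0,\sigma)\;\otimes_t\;
\Gamma(t;\,a, k, \tau, d),$$

with $G$ a zero-mean Gaussian of width $\sigma = 0.15$ mm and $\Gamma$ a
gamma kernel $a\,((t-d)/\tau)^{k-1} e^{-(t-d)/\tau}$ peaking at
$d + (k-1)\tau$. Both signals are baseline-normalized percent changes
($\Delta I$, $\Delta SR$) so the model is unit-free up to the calibration
slope.

## Signals and their normalization

A trial lasts 34 s at 5 Hz (170 frames): 10 s baseline, 4 s stimulus
(full-field flickering checkerboard at one of six contrasts: 0, 5, 10,
30, 50, 100%), 20 s recovery. Spikes are summed over groups of five
probe contacts (100 µm, matching the Doppler depth pitch) into 0.2-s
half-open bins `[t, t + 0.2)`. `compute_delta()` divides each per-trial
trace by its own baseline mean; this makes every downstream quantity
invariant to the arbitrary scale of the raw Doppler units and of absolute
firing rates, which is asserted by property tests. Trials with a zero
baseline are flagged invalid and excluded rather than propagating
infinities.

Per-contrast response curves (maximum of the trial-averaged trace after
stimulus onset) are compared across sessions and regions after a two-step
normalization (`normalize_curve_max()`): a per-curve z-score across
contrasts, then one affine rescale of all pooled values onto [0, 1]. The
maximum is taken over the whole post-onset window by default — the
hemodynamic peak lags the stimulus by roughly the kernel width, so a
stimulus-window maximum would truncate it; `contrast_maxima()` exposes the
stricter window as an option.

## Probe alignment

The B-mode estimate of the probe trajectory is only approximate (the
shank's echo is ~3 voxels wide, and the tip may sit off-plane), so the
alignment samples 10,000 candidates around it: integer tip shifts
$\delta, \theta \in [-5, 5]$ voxels and a slope perturbation
$\varepsilon \in [-0.2, 0.2]$, with out-of-grid candidates rejected and
resampled, and the unperturbed initial always injected so the selected
score can never fall below it. Each candidate is scored by the Pearson
correlation between the trial-averaged $\Delta I$ at its voxels and the
first $N$ spike depth bins from the tip, at the highest contrast (best
signal-to-noise). Two arrangements are offered: the default concatenates
the full bin-by-frame matrices; the alternative (`binmean`) correlates
per-bin time means, i.e. the purely spatial profiles. The concatenated
score is bounded away from 1 even on noiseless data — the Doppler time
course is the *convolved, delayed* copy of the spike time course — while
the `binmean` score approaches 1 there; both select the same trajectory.
Exact ties (e.g. on a spatially uniform field) resolve to the lowest
candidate index, deterministically.

Two geometric facts matter when interpreting tip accuracy. First, a
candidate that shifts the tip but counter-rotates about the center of the
active region passes through nearly the same voxels where the signal
lives; such candidates are legitimately near-equivalent, and the package's
displacement analyses therefore measure trajectories as voxel paths, not
tip labels. Second, for a perfectly vertical probe in a laterally smooth
field, a pure lateral shift rescales every extracted trace by a common
factor, which a correlation cannot see — resolving it requires lateral
structure in the field, which the generator provides (see below).

## Transfer-function estimation

`build_design()` stacks, for every frame $t$ with a complete window, the
spike-rate changes at lags 0…20 (a 4-s causal window at 0.2 s per frame)
as one row, with $\Delta I(t)$ as the response, across all contrast
conditions; `fit_tf()` solves the ridge problem
$\min \lVert y - X\beta - \beta_0\rVert^2 + \lambda \lVert \beta \rVert^2$
with an unpenalized intercept, by centered normal equations. At
$\lambda = 0$ on a full-rank design this reproduces ordinary least squares
to 1e-8, which is tested; a singular design at $\lambda = 0$ errors with
instructions rather than silently pseudo-inverting. The penalty defaults
to leave-one-contrast-out cross-validation over a log-spaced grid
(`10^seq(-4, 4)`), a reproducible data-driven choice; a fixed override is
available. On the synthetic sessions the fit is insensitive to $\lambda$
over many orders of magnitude because the stimulus-locked signal subspace
dominates.

The estimated kernel is summarized by its time-to-peak and FWHM. The FWHM
follows strict sample counting — the longest run of coefficients strictly
above half the peak, times 0.2 s — with a sub-sample interpolated variant
behind a flag (needed, e.g., to resolve the 0.061-mm analytic widening of
a 1-mm Gaussian convolved at σ = 0.15 mm). For time-to-peak the package
distinguishes traces from kernels: on trial-averaged response traces the
default is the first local maximum after onset ("first inflection" rules
are ambiguous for discrete noisy data; the first-peak reading matches the
~0.8-s kernel peaks), while `tf_metrics()` uses the first occurrence of
the global maximum, because single-sample local maxima of ridge
coefficients are noise and the model kernel is unimodal — on a noiseless
kernel the two readings coincide. `fit_gamma()` then fits the
four-parameter gamma form by Levenberg-Marquardt with box constraints
($k > 1$, $\tau > 0$, $d \ge 0$), started from the empirical peak and
width; on exactly sampled kernels it recovers the parameters to machine
precision.

## Spatial spread

For the spatial comparison each depth bin is reduced to its response
amplitude during the stimulus window. Two reductions are provided: the
maximum (used for the descriptive peak-aligned correlation and ΔFWHM
comparison) and the window mean. For *kernel-width recovery* the mean is
the right choice: a linear reduction commutes with the spatial
convolution, so the Doppler profile is exactly the blurred spike profile
in expectation, whereas the maximum of a noisy trace carries an
SNR-dependent upward bias that distorts the fitted width. The Doppler
value per bin is the mean of the ±3-voxel lateral band (the same strip
the region traces use), which suppresses both noise and the sub-voxel
jitter of a tilted shank. `fit_spatial_sigma()` then finds σ minimizing
the residual of `ΔI_profile ~ gain · blur(ΔSR_profile, σ) + offset`,
jointly with an integer shift of up to ±3 bins that absorbs residual
alignment error.

## The synthetic generator and what it does (not) emulate

`gen_session()` co-simulates both modalities with known truth:

- **Spiking**: Poisson counts per 100-µm bin and 0.2-s frame around a
  basal rate, plus a stimulus-locked increment
  $r(c) = r_{max} c^n / (c^n + c_{50}^n)$ (Naka-Rushton; defaults
  $r_{max} = 10$ spikes/s, $c_{50} = 20$%, $n = 1.5$, chosen to give the
  monotone saturating contrast curves seen in visual areas). The depth
  profile of the increment is a Gaussian lobe (FWHM 1 mm) centered
  mid-trajectory plus a secondary lobe of relative amplitude 0.35 (FWHM
  0.6 mm) towards the tip. The second lobe emulates the layered response
  structure of visual targets; it stays below half-maximum so FWHM-based
  metrics see only the main lobe, and it anchors the rotational degree of
  freedom of the alignment, which a single symmetric lobe leaves
  unidentifiable (tip-shift and counter-rotation then tie to ~1e-4 in
  correlation).
- **Hemodynamics**: the percent-change spike field of each trial — by
  default the *realized* Poisson rates, since blood volume follows actual
  neural activity (the noiseless mean-rate drive of the idealized model
  is available as `drive = "mean"`) — convolved with the region's
  unit-peak gamma kernel in time and painted onto the grid with the
  σ = 0.15 mm Gaussian, laterally centered on the shank's continuous
  (un-rounded) position. A static per-voxel log-normal sensitivity gain
  (`gain_sd = 0.15`) emulates vascular heterogeneity of the Doppler
  signal; without it the painted field is laterally separable and probe
  alignment is ill-posed (see above). The field is scaled so that the
  ratio of region-averaged trace maxima equals the region's calibration
  slope — the trace level is what the slope is measured on — then
  per-voxel Gaussian noise (default SD 5% ΔI per voxel-frame) is added
  and intensity reconstructed as $I = I_0 (1 + \Delta I / 100)$ around an
  arbitrary positive baseline.
- **Region truths**: collicular config — 30 bins, basal 4.50 spikes/s,
  slope 21.4, kernel FWHM 1.5 s; geniculate — 25 bins, 10.36 spikes/s,
  slope 7.7, FWHM 0.8 s; cortical — 25 bins, 6.79 spikes/s, slope 10.5,
  FWHM 1.5 s. All kernels peak 0.8 s after onset with zero delay; shapes
  are solved analytically from (peak, FWHM), giving k = 2.65, τ = 0.484 s
  and k = 6.62, τ = 0.142 s. Sampled at 0.2 s, the longest-run FWHM of
  the true kernels is 1.4 s and 0.8 s.

With all stochastic switches off (`poisson = FALSE`, `drive = "mean"`,
`noise_sd = 0`, `gain_sd = 0`) the generated movie equals the forward
model exactly on a vertical trajectory, the calibration ratio is exact,
and a zero-contrast session is identically flat — the anchor tests of the
suite.

What the generator does **not** emulate: probe drift and tissue motion
(no motion correction exists in the pipeline), spike-sorting errors,
correlated (vascular, cardiac, respiratory) Doppler noise — noise is
i.i.d. Gaussian per voxel-frame, which real clutter-filtered Power-Doppler
only approximates — off-plane trajectories, negative hemodynamic
responses, and nonlinear or state-dependent coupling. Passing recovery
tests therefore demonstrates correctness of the estimators under the
model's own assumptions, not robustness to every artifact of animal data.

## Session inclusion and group statistics

A session is kept when (1) at the highest contrast the stimulus-window
mean exceeds the baseline mean across trials for *both* modalities
(one-sided paired t-test, α = 0.05 — "significant response" needs an
operational definition and this is the simplest one consistent with
trial-level resampling), and (2) the trajectory crosses the target region.
Between-region comparisons use uncorrected pairwise t-tests or a
Kruskal-Wallis omnibus, as is conventional for these session-level
contrasts; quartile displays use the linear-interpolation convention
(`quantile(type = 7)`).

## Problem sizes and reproducibility

The recovery studies (`recovery_study()`, the acceptance script, and the
acceptance tests) use 20 sessions per configuration with 6 contrasts × 20
trials on a probe-centered 143 × 32 field of view — lateral voxels beyond
~1.3 mm from the shank enter no trajectory-, band- or profile-based
quantity, so the crop changes no analyzed number while keeping a study in
the minutes range; the generator's own defaults remain the full 143 × 128
grid and 50 trials per contrast. Every stochastic step (trial order,
Poisson spiking, gains, noise, candidate sampling) runs under a single
seed through one RNG stream, so identical configurations and seeds
reproduce results bit for bit; per-session seeds are drawn once from the
study's master seed.

## Known limitations

- The temporal kernel is identified from stimulus-locked variance plus
  the shared trial-to-trial spiking fluctuations; with a 4-s boxcar
  stimulus alone (noise-free drive) the kernel would only be constrained
  at the stimulus harmonics.
- Tip position along the shank is weakly identified compared to the
  trajectory's path through the active region; accuracy claims are
  therefore stated for the path (and the tip only to ±1 voxel under
  noise).
- The calibration slope is defined at the region-trace level; per-voxel
  slopes vary with local sensitivity and are not modeled.
- `fwhm()`'s strict counting quantizes widths to the sample step; means
  across sessions mitigate but do not remove the quantization.
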
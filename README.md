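# fuscouple

Quantifying neurovascular coupling between **functional ultrasound (fUS)
Power-Doppler imaging** and **Neuropixels spike trains** recorded
simultaneously in the mouse visual pathway (superior colliculus, lateral
geniculate nucleus, primary visual cortex).

fUS measures cerebral blood volume through the Power-Doppler intensity
I(x, y, t) on a voxel grid at 5 Hz; a Neuropixels probe crossing the same
tissue yields spike rates along its shank. After matching resolutions
(spikes summed over 5 contacts = 100 µm depth bins, 200 ms time bins) and
normalizing both signals to their pre-stimulus baselines,

    ΔSR = 100 · (SR − SR_basal) / SR_basal,
    ΔI  = 100 · (I − I_basal) / I_basal,

the package implements the full analysis chain that links them:

- **Probe alignment** — Monte-Carlo search over 10,000 perturbed
  trajectories (tip shifts δ, θ ∈ ⟦−5, 5⟧ voxels, slope jitter
  ε ∈ [−0.2, 0.2]), selecting the candidate maximizing the Pearson
  correlation between the ΔI values extracted along it and the first N
  spike-rate depth bins from the tip (N = 30 collicular, 25 thalamic /
  cortical insertions).
- **Region averaging** — fUS voxels within a ±3-voxel lateral band around
  the trajectory intersected with the region label; spike bins inside the
  region; one trace per contrast condition (0, 5, 10, 30, 50, 100%).
- **Amplitude calibration** — per-contrast maxima of ΔSR regressed on
  maxima of ΔI; the slope is the region's conversion factor (% spike-rate
  change per 1% Doppler change).
- **Temporal transfer function** — lag-stacked ridge regression: each row
  of the design holds ΔSR(t−20)…ΔSR(t) (21 taps, 0.2 s each, a 4-s
  window), the response is ΔI(t), rows stacked across contrasts; the
  coefficient vector is the causal coupling kernel, summarized by its
  time-to-peak and FWHM (longest run above half peak × 0.2 s) and fitted
  with a gamma parameterization a·((t−d)/τ)^(k−1)·e^(−(t−d)/τ).
- **Spatial spread** — per-bin response profiles along the probe compared
  after peak alignment (Pearson r, ΔFWHM in mm) and the width σ of the
  spatial Gaussian coupling kernel recovered by least squares.
- **Forward model** — ΔI(x, t) = ΔSR(x, t) ⊗ₓ G(x; 0, σ) ⊗ₜ Γ(t; θ), the
  separable spatiotemporal model combining the Gaussian spatial kernel
  (σ = 0.15 mm) with the region's temporal gamma kernel.

Because the matched animal recordings cannot be regenerated at a desk, the
package ships a first-class **synthetic session generator**
(`gen_session()`): Poisson spiking over a basal rate with a Naka-Rushton
contrast response and a layered depth profile, hemodynamics produced by the
forward model from the realized spikes, painted onto a 143 × 128 voxel
grid (100 × 80 µm pitch) with per-voxel sensitivity heterogeneity and
Gaussian noise, over 34-s trials (10 s baseline / 4 s stimulus / 20 s
post; 170 frames at 5 Hz). Every downstream stage is validated by
parameter recovery against the generator's ground truth.

## Worked example

```r
library(fuscouple)

# a collicular-like synthetic session: slope 21.4, kernel peak 0.8 s /
# FWHM 1.5 s, basal rate 4.50 spikes/s, sigma 0.15 mm
cfg <- session_config(
  region = sc_config(), grid_dim = c(143, 32),
  n_trials = 20, noise_sd = 5
)
s <- gen_session(cfg, seed = 11)

# start alignment from a deliberately wrong initial estimate
init <- probe_trajectory(
  s$trajectory$tip_col + 2, s$trajectory$tip_row - 2,
  s$trajectory$slope + 0.08, s$trajectory$n_bins
)
pl <- run_session_pipeline(s, init, n_candidates = 10000, seed = 11)
pl$result[, c("slope", "r2_amp", "tf_time_to_peak_s", "tf_fwhm_s", "sigma_mm")]
#> # A tibble: 1 × 5
#>   slope r2_amp tf_time_to_peak_s tf_fwhm_s sigma_mm
#>   <dbl>  <dbl>             <dbl>     <dbl>    <dbl>
#> 1  22.4  0.995               0.8       1.4    0.120
```

The recovered calibration slope (22.4 %ΔSR per %ΔI against a generator
truth of 21.4), transfer-function peak (0.8 s) and width (1.4 s, equal to
the sampled-kernel truth) come back from one noisy movie within a few
percent; the spatial kernel width scatters more on a single session
(0.120 mm here against 0.15 mm) and is recovered to within 0.003 mm on
average over a 20-session study. `r2_amp` is the R² of the amplitude
calibration across the six contrasts.

Fitted objects follow broom conventions — `tidy(pl$tf)` gives the
coefficient-per-lag table, `glance(pl$amp)` the calibration summary — and
have `autoplot()` methods; `plot_correlation_map()`,
`plot_region_traces()` and `plot_spatial_profiles()` cover the standard
displays.

Multi-session studies aggregate with

```r
res <- recovery_study(sc_config(), n_sessions = 20, seed = 1)
study_report(res)
```

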
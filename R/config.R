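#' Contrast-response function (Naka-Rushton)
#'
#' Maps stimulus contrast (%) to the stimulus-driven firing-rate increment,
#' r(c) = r_max * c^n / (c^n + c50^n): zero at zero contrast, monotone, and
#' saturating towards `r_max`, the standard saturating form for visual
#' contrast-response curves.
#'
#' @param contrast Contrast in percent (>= 0; vectorized).
#' @param crf List with `r_max_hz`, `c50`, `n` (see [crf_params()]).
#' @return Rate increment in spikes/s.
#' @export
contrast_response <- function(contrast, crf) {
  if (any(contrast < 0)) stop("contrast must be >= 0", call. = FALSE)
  cn <- contrast^crf$n
  out <- crf$r_max_hz * cn / (cn + crf$c50^crf$n)
  out[contrast == 0] <- 0
  out
}

#' Contrast-response parameters
#'
#' @param r_max_hz Saturating rate increment (spikes/s).
#' @param c50 Semi-saturation contrast (%).
#' @param n Hill exponent.
#' @return A list usable as the `crf` argument of [contrast_response()].
#' @export
crf_params <- function(r_max_hz = 10, c50 = 20, n = 1.5) {
  stopifnot(r_max_hz > 0, c50 > 0, n > 0)
  list(r_max_hz = r_max_hz, c50 = c50, n = n)
}

#' Region generator configurations
#'
#' Ground-truth settings for the three visual-pathway targets. Basal firing
#' rates per 100-um depth bin, amplitude-calibration slopes (% spike-rate
#' change per % Doppler change) and temporal-kernel widths follow the
#' region-specific values measured in awake mouse recordings: the colliculus
#' couples with a large slope (low basal rate), the geniculate with a small
#' one, and the kernels share a 0.8-s peak but differ in width (1.5 s vs
#' 0.8 s FWHM). Trajectory lengths: 30 bins (SC) or 25 (LGN, V1).
#'
#' @param name Region label.
#' @param n_bins Trajectory depth bins.
#' @param basal_rate_hz Basal rate per depth bin (spikes/s).
#' @param slope_amp Amplitude-calibration slope (% dSR per % dI).
#' @param gamma A [gamma_params()] temporal kernel (unit peak; the overall
#'   coupling gain is set by `slope_amp`).
#' @param crf [crf_params()] of the contrast-response function.
#' @return A list of class `region_config`.
#' @export
region_config <- function(name, n_bins, basal_rate_hz, slope_amp,
                          gamma, crf = crf_params()) {
  stopifnot(basal_rate_hz > 0, slope_amp > 0, inherits(gamma, "gamma_params"))
  structure(
    list(
      name = name, n_bins = as.integer(n_bins),
      basal_rate_hz = basal_rate_hz, slope_amp = slope_amp,
      gamma = gamma, crf = crf
    ),
    class = "region_config"
  )
}

#' @rdname region_config
#' @export
sc_config <- function() {
  region_config(
    name = "SC", n_bins = 30, basal_rate_hz = 4.50, slope_amp = 21.4,
    gamma = gamma_params_for_fwhm(fwhm_s = 1.5, peak_s = 0.8)
  )
}

#' @rdname region_config
#' @export
lgn_config <- function() {
  region_config(
    name = "LGN", n_bins = 25, basal_rate_hz = 10.36, slope_amp = 7.7,
    gamma = gamma_params_for_fwhm(fwhm_s = 0.8, peak_s = 0.8)
  )
}

#' @rdname region_config
#' @export
v1_config <- function() {
  region_config(
    name = "V1", n_bins = 25, basal_rate_hz = 6.79, slope_amp = 10.5,
    gamma = gamma_params_for_fwhm(fwhm_s = 1.5, peak_s = 0.8)
  )
}

#' Synthetic session configuration
#'
#' Gathers everything that determines a synthetic recording session: the
#' trial timeline, the voxel grid, the contrast protocol, the region ground
#' truth and the noise model. Together with a seed this fully determines
#' the generated arrays.
#'
#' @param region A [region_config()] (ground truth for the recorded region).
#' @param timeline A [trial_timeline()].
#' @param grid_dim `c(n_rows, n_cols)` of the Doppler image (default
#'   143 x 128 voxels).
#' @param pitch_mm `c(row_pitch, col_pitch)` voxel pitch in mm. Rows are the
#'   depth axis at 0.1 mm (matching the 100-um spike depth bins), columns
#'   the lateral axis at 0.08 mm.
#' @param contrasts Contrast conditions in percent (subset of \[0, 100\]).
#' @param n_trials Trials per contrast condition.
#' @param noise_sd SD of additive Gaussian noise on per-voxel per-frame
#'   Doppler percent change (units of % dI).
#' @param gain_sd SD (log scale) of a static per-voxel multiplicative gain
#'   on the hemodynamic signal, emulating vascular-density heterogeneity of
#'   the Doppler sensitivity; mean-1 log-normal, fixed across frames and
#'   trials. 0 disables (the painted field is then laterally separable and
#'   correlation-based alignment cannot resolve pure lateral shifts of a
#'   vertical probe).
#' @param sigma_mm SD of the spatial Gaussian coupling kernel (mm).
#' @param profile_fwhm_mm FWHM of the main Gaussian lobe of the depth
#'   profile of the stimulus-driven rate increment (mm), centered
#'   mid-trajectory.
#' @param profile2_amp Relative amplitude of a secondary, weaker response
#'   lobe towards the tip, emulating the layered depth structure of visual
#'   targets (deep lobes respond less than superficial ones). Kept below
#'   0.5 so half-maximum widths are set by the main lobe alone; it also
#'   anchors the trajectory's rotational degree of freedom during
#'   alignment, which a single symmetric lobe leaves free. 0 disables.
#' @param profile2_center_frac Position of the secondary lobe along the
#'   trajectory, as a fraction of the bin count from the tip.
#' @param profile2_fwhm_mm FWHM of the secondary lobe (mm).
#' @param basal_intensity Arbitrary positive baseline Doppler intensity used
#'   to reconstruct I from dI (absolute units cancel downstream).
#' @param poisson If `FALSE`, Poisson spiking is replaced by its mean
#'   (deterministic expected counts).
#' @param drive `"spikes"` drives the hemodynamics with the realized spike
#'   rates; `"mean"` with the noiseless mean-rate field.
#' @param tip,slope Tip voxel `c(col, row)` and slope of the true trajectory;
#'   defaults center the trajectory in the grid with a slight tilt.
#' @param region_halfwidth Lateral half-width (columns) of the rectangular
#'   region label around the trajectory.
#' @return A list of class `session_config`.
#' @export
session_config <- function(region = sc_config(),
                           timeline = trial_timeline(),
                           grid_dim = c(143, 128),
                           pitch_mm = c(0.1, 0.08),
                           contrasts = c(0, 5, 10, 30, 50, 100),
                           n_trials = 50,
                           noise_sd = 5,
                           gain_sd = 0.15,
                           sigma_mm = 0.15,
                           profile_fwhm_mm = 1.0,
                           profile2_amp = 0.35,
                           profile2_center_frac = 0.2,
                           profile2_fwhm_mm = 0.6,
                           basal_intensity = 1000,
                           poisson = TRUE,
                           drive = c("spikes", "mean"),
                           tip = NULL, slope = 0.1,
                           region_halfwidth = 10) {
  drive <- match.arg(drive)
  if (length(contrasts) == 0) stop("contrast list is empty", call. = FALSE)
  if (any(contrasts < 0 | contrasts > 100)) {
    stop("contrasts must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(
    inherits(region, "region_config"), inherits(timeline, "trial_timeline"),
    n_trials >= 1, noise_sd >= 0, gain_sd >= 0, sigma_mm >= 0,
    basal_intensity > 0
  )
  if (is.null(tip)) {
    tip <- c(
      floor(grid_dim[2] / 2),
      floor((grid_dim[1] + region$n_bins) / 2)
    )
  }
  traj <- gen_trajectory(grid_dim, tip, slope, region$n_bins) # validates
  structure(
    list(
      region = region, timeline = timeline, grid_dim = as.integer(grid_dim),
      pitch_mm = pitch_mm, contrasts = contrasts,
      n_trials = as.integer(n_trials),
      noise_sd = noise_sd, gain_sd = gain_sd, sigma_mm = sigma_mm,
      profile_fwhm_mm = profile_fwhm_mm,
      profile2_amp = profile2_amp,
      profile2_center_frac = profile2_center_frac,
      profile2_fwhm_mm = profile2_fwhm_mm,
      basal_intensity = basal_intensity,
      poisson = poisson, drive = drive,
      trajectory = traj, region_halfwidth = as.integer(region_halfwidth)
    ),
    class = "session_config"
  )
}
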
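#' Generate a synthetic fUS + Neuropixels session
#'
#' Co-simulates spiking and hemodynamics with known ground truth. Per depth
#' bin the firing rate is `basal + r(contrast) * profile(depth)` during the
#' stimulus window (Poisson counts in 0.2-s bins, or their mean when
#' `poisson = FALSE`). The percent spike-rate change field is pushed through
#' the spatiotemporal forward model -- a causal temporal gamma kernel per
#' bin, painted onto the voxel grid with a Gaussian spatial spread around
#' the true trajectory -- then scaled so the region-averaged trace maxima
#' satisfy `max dSR / max dI = slope_amp`, and corrupted with additive
#' Gaussian voxel noise. Doppler intensity is reconstructed around a
#' positive baseline as `I = I0 * (1 + dI / 100)`.
#'
#' With `drive = "spikes"` (default) the hemodynamics follow the realized
#' spike rates, as blood volume follows actual neural activity; with
#' `drive = "mean"` they follow the noiseless mean-rate field, in which case
#' a zero-contrast, zero-noise session has identically zero dI.
#'
#' @param config A [session_config()].
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `fus_session`: a list with
#'   \describe{
#'     \item{doppler}{array `[row, col, frame, trial]` of Doppler intensity}
#'     \item{spikes}{array `[bin, frame, trial]` of spike counts per 0.2-s
#'       bin (100-um depth bins, tip first)}
#'     \item{trials}{tibble `trial`, `contrast` (randomized order)}
#'     \item{mask}{integer region-label matrix (0 background, 1 target)}
#'     \item{region_names}{named id -> name map}
#'     \item{trajectory}{the true [probe_trajectory()]}
#'     \item{timeline}{the [trial_timeline()]}
#'     \item{truth}{generator ground truth (slope, kernel, sigma, basal
#'       rate, depth profile, calibration scale)}
#'     \item{config, seed}{provenance}
#'   }
#' @export
gen_session <- function(config, seed) {
  stopifnot(inherits(config, "session_config"), length(seed) == 1)
  withr::with_seed(as.integer(seed), gen_session_impl(config, seed))
}

gen_session_impl <- function(config, seed) {
  tl <- config$timeline
  reg <- config$region
  gd <- config$grid_dim
  nF <- tl$n_frames
  bin_s <- tl$frame_s
  tv <- trajectory_voxels(config$trajectory, gd)
  n_bins <- nrow(tv)
  n_total <- length(config$contrasts) * config$n_trials

  # region label: rectangle spanning the trajectory rows, widened laterally
  mask <- matrix(0L, gd[1], gd[2])
  cols <- max(1L, min(tv$col) - config$region_halfwidth):
    min(gd[2], max(tv$col) + config$region_halfwidth)
  mask[min(tv$row):max(tv$row), cols] <- 1L
  if (!any(mask[cbind(tv$row, tv$col)] == 1L)) {
    stop("target region absent from mask", call. = FALSE)
  }

  contrast_seq <- rep(config$contrasts, each = config$n_trials)
  trials <- tibble::tibble(
    trial = seq_len(n_total),
    contrast = contrast_seq[sample.int(n_total)]
  )

  # depth profile of the stimulus-driven increment: main Gaussian lobe
  # centered mid-trajectory plus an optional weaker lobe towards the tip
  # (layered response structure; also pins the rotational degree of
  # freedom in trajectory alignment)
  to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2))) / config$pitch_mm[1]
  bins <- seq_len(n_bins)
  profile <- exp(-(bins - (n_bins + 1) / 2)^2 / (2 * to_sd(config$profile_fwhm_mm)^2))
  if (config$profile2_amp > 0) {
    c2 <- 1 + config$profile2_center_frac * (n_bins - 1)
    profile <- profile + config$profile2_amp *
      exp(-(bins - c2)^2 / (2 * to_sd(config$profile2_fwhm_mm)^2))
  }

  boxcar <- stimulus_boxcar(tl)
  r_inc <- contrast_response(config$contrasts, reg$crf)
  names(r_inc) <- as.character(config$contrasts)
  if (any(reg$basal_rate_hz + r_inc * max(profile) <= 0)) {
    stop("non-positive firing rate", call. = FALSE)
  }

  # spike counts [bin, frame, trial]
  spikes <- array(0, dim = c(n_bins, nF, n_total))
  for (i in seq_len(n_total)) {
    lam <- (reg$basal_rate_hz +
      r_inc[[as.character(trials$contrast[i])]] * outer(profile, boxcar)) *
      bin_s
    spikes[, , i] <- if (config$poisson) {
      array(stats::rpois(length(lam), lam), dim = dim(lam))
    } else {
      lam
    }
  }

  # spatial painting weights: depth Gaussian (unit sum) x lateral Gaussian
  # (unit peak), so the on-trajectory field of a vertical probe equals the
  # 1-D depth-convolved forward model exactly
  wd <- gaussian_taps(config$sigma_mm / config$pitch_mm[1])
  wl_r <- max(1L, ceiling(4 * config$sigma_mm / config$pitch_mm[2]))
  wl_off <- seq(-wl_r, wl_r)
  rd <- max(abs(attr(wd, "offsets")))
  win_rows <- max(1L, min(tv$row) - rd):min(gd[1], max(tv$row) + rd)
  win_cols <- max(1L, min(tv$col) - wl_r):min(gd[2], max(tv$col) + wl_r)
  nwr <- length(win_rows)
  nwc <- length(win_cols)
  # W[(row-fastest voxel), bin]; the lateral Gaussian is centered on the
  # probe's continuous lateral position (the shank is not snapped to the
  # voxel grid), the depth axis on the integer bin rows
  W <- matrix(0, nwr * nwc, n_bins)
  wd_off <- attr(wd, "offsets")
  traj <- config$trajectory
  for (b in seq_len(n_bins)) {
    ctr <- traj$tip_col + (b - 1) * traj$slope
    cc <- round_half_up(ctr) + wl_off
    wl_b <- if (config$sigma_mm > 0) {
      exp(-((cc - ctr) * config$pitch_mm[2])^2 / (2 * config$sigma_mm^2))
    } else {
      as.numeric(cc == tv$col[b])
    }
    dr <- match(tv$row[b] + wd_off, win_rows)
    dc <- match(cc, win_cols)
    okr <- !is.na(dr)
    okc <- !is.na(dc)
    W[as.vector(outer(dr[okr], (dc[okc] - 1L) * nwr, "+")), b] <-
      as.vector(outer(wd[okr], wl_b[okc]))
  }

  taps <- sample_gamma_kernel(reg$gamma, step_s = bin_s)

  # static per-voxel Doppler sensitivity gains (vascular heterogeneity)
  gains <- if (config$gain_sd > 0) {
    exp(stats::rnorm(nwr * nwc, 0, config$gain_sd) - config$gain_sd^2 / 2)
  } else {
    rep(1, nwr * nwc)
  }

  # calibration: region-averaged trace maxima at the highest contrast
  cmax <- max(config$contrasts)
  inc_max <- r_inc[[as.character(cmax)]] * outer(profile, boxcar)
  dsr_mean <- 100 * inc_max / reg$basal_rate_hz # [bin, frame]
  in_region <- mask[cbind(tv$row, tv$col)] == 1L
  sr_trace <- colMeans(dsr_mean[in_region, , drop = FALSE])
  conv_mean <- t(causal_conv(t(dsr_mean), taps)) # [bin, frame]
  band_idx <- band_voxel_indices(tv, mask, band = 3, win_rows, win_cols)
  di_trace <- colMeans((gains * (W %*% conv_mean))[band_idx, , drop = FALSE])
  scale <- if (max(di_trace) > 0) {
    max(sr_trace) / (reg$slope_amp * max(di_trace))
  } else {
    1
  }

  # Doppler: noise first (one draw), then add the painted signal per trial
  doppler <- if (config$noise_sd > 0) {
    stats::rnorm(prod(gd) * nF * n_total, sd = config$noise_sd)
  } else {
    numeric(prod(gd) * nF * n_total)
  }
  dim(doppler) <- c(gd[1], gd[2], nF, n_total)
  for (i in seq_len(n_total)) {
    dsr_i <- if (config$drive == "spikes") {
      100 * (spikes[, , i] / bin_s - reg$basal_rate_hz) / reg$basal_rate_hz
    } else {
      100 * r_inc[[as.character(trials$contrast[i])]] *
        outer(profile, boxcar) / reg$basal_rate_hz
    }
    field <- scale * (gains * (W %*% t(causal_conv(t(dsr_i), taps))))
    doppler[win_rows, win_cols, , i] <-
      doppler[win_rows, win_cols, , i] +
      array(field, dim = c(nwr, nwc, nF))
  }
  # reconstruct intensity around the basal level
  doppler <- doppler * (config$basal_intensity / 100)
  doppler <- doppler + config$basal_intensity

  structure(
    list(
      doppler = doppler, spikes = spikes, trials = trials,
      mask = mask, region_names = stats::setNames(reg$name, "1"),
      trajectory = config$trajectory, timeline = tl,
      truth = list(
        slope_amp = reg$slope_amp, gamma = reg$gamma,
        sigma_mm = config$sigma_mm, basal_rate_hz = reg$basal_rate_hz,
        profile = profile, scale = scale, kernel_taps = taps,
        gain_sd = config$gain_sd,
        crf = reg$crf, noise_sd = config$noise_sd
      ),
      config = config, seed = seed
    ),
    class = "fus_session"
  )
}

#' @export
print.fus_session <- function(x, ...) {
  cat(sprintf(
    "<fus_session> %s | %d x %d voxels, %d frames, %d trials (%s%%)\n",
    x$config$region$name, dim(x$doppler)[1], dim(x$doppler)[2],
    x$timeline$n_frames, nrow(x$trials),
    paste(x$config$contrasts, collapse = "/")
  ))
  invisible(x)
}

# linear indices (within the window) of voxels in the +/- band lateral
# extension of the trajectory, intersected with the region mask
band_voxel_indices <- function(tv, mask, band, win_rows, win_cols) {
  nwr <- length(win_rows)
  idx <- integer(0)
  for (b in seq_len(nrow(tv))) {
    cc <- (tv$col[b] - band):(tv$col[b] + band)
    cc <- cc[cc >= 1 & cc <= ncol(mask)]
    cc <- cc[mask[tv$row[b], cc] == 1L]
    ri <- match(tv$row[b], win_rows)
    ci <- match(cc, win_cols)
    ok <- !is.na(ci) & !is.na(ri)
    idx <- c(idx, ri + (ci[ok] - 1L) * nwr)
  }
  unique(idx)
}
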
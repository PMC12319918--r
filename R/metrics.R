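#' Time to peak of a response
#'
#' Latency from stimulus onset to the response maximum, in seconds.
#' `mode = "first_peak"` (default) returns the first local maximum at or
#' after the onset frame (a plateau counts from its first sample; of two
#' equal maxima the earlier wins); a trace that rises monotonically to its
#' last sample has no peak and returns `NA`. `mode = "global"` returns the
#' first occurrence of the window maximum, the robust choice for noisy
#' unimodal kernels.
#'
#' @param x Numeric trace.
#' @param onset_frame 1-based index of the stimulus-onset frame.
#' @param step_s Frame step in seconds.
#' @param mode `"first_peak"` or `"global"`.
#' @return Seconds relative to onset, or `NA` if no peak exists.
#' @export
#' @examples
#' time_to_peak(c(0, 0, 1, 5, 2, 1), onset_frame = 2, step_s = 0.2) # 0.4
time_to_peak <- function(x, onset_frame, step_s = 0.2,
                         mode = c("first_peak", "global")) {
  mode <- match.arg(mode)
  stopifnot(onset_frame >= 1, onset_frame <= length(x))
  w <- x[onset_frame:length(x)]
  if (mode == "global") {
    return((which.max(w) - 1) * step_s)
  }
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    rises <- i == 1L || r$values[i] > r$values[i - 1L]
    falls <- i < length(r$values) && r$values[i] > r$values[i + 1L]
    if (rises && falls) {
      return((starts[i] - 1) * step_s)
    }
  }
  NA_real_
}

#' Full width at half maximum by sample counting
#'
#' Length of the longest run of consecutive samples strictly above half the
#' peak amplitude, times the sample step. With `interpolate = TRUE` the
#' width is instead measured between linearly interpolated half-maximum
#' crossings around the peak (sub-sample precision).
#'
#' @param x Numeric signal (temporal trace or spatial profile).
#' @param step Sample step (0.2 s for frames, 0.1 mm for depth bins).
#' @param interpolate Use linear interpolation of the half-max crossings.
#' @return Width in `step` units. Errors if the signal has no positive
#'   peak.
#' @export
#' @examples
#' fwhm(c(0, 0, 1, 1, 1, 0), step = 0.2) # 0.6
fwhm <- function(x, step = 1, interpolate = FALSE) {
  peak <- max(x)
  if (!is.finite(peak) || peak <= 0) {
    stop("signal has no positive peak", call. = FALSE)
  }
  half <- peak / 2
  if (!interpolate) {
    above <- x > half
    r <- rle(above)
    return(max(r$lengths[r$values]) * step)
  }
  p <- which.max(x)
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(p - 1)) else seq(p + 1, length(x))
    if (p == 1 && side == "left") {
      return(p - 0.5)
    }
    if (p == length(x) && side == "right") {
      return(p + 0.5)
    }
    for (i in idx) {
      if (x[i] <= half) {
        j <- if (side == "left") i + 1L else i - 1L
        frac <- (x[j] - half) / (x[j] - x[i])
        return(if (side == "left") j - frac else j + frac)
      }
    }
    if (side == "left") 0.5 else length(x) + 0.5
  }
  (cross("right") - cross("left")) * step
}

#' Drop high outliers from a collection of metric values
#'
#' Removes values above `mean + 2 * sd` of the collection, the rule used
#' when pooling per-session time-to-peak and FWHM values.
#'
#' @param x Numeric vector.
#' @return `x` without values exceeding the threshold.
#' @export
remove_outliers <- function(x) {
  if (length(x) < 2) {
    return(x)
  }
  x[x <= mean(x) + 2 * stats::sd(x)]
}

#' Amplitude calibration between modalities
#'
#' Ordinary least squares of the per-contrast spike-rate maxima on the
#' Doppler maxima: the slope is the percent spike-rate change associated
#' with a 1% increase of the Doppler response maximum.
#'
#' @param df Data frame with one row per contrast.
#' @param max_i,max_sr Columns holding the per-contrast maxima of dI and
#'   dSR (tidy-evaluated; defaults `max_i`, `max_sr`).
#' @return Object of class `amp_calibration` wrapping the `lm` fit, with
#'   `slope`, `intercept`, `r_squared`, `n` and the data. Requires >= 3
#'   contrast points and non-constant `max_i`.
#' @export
#' @examples
#' d <- tibble::tibble(max_i = c(0, 1, 2, 4), max_sr = 7.7 * c(0, 1, 2, 4))
#' amplitude_regression(d)$slope # 7.7
amplitude_regression <- function(df, max_i = max_i, max_sr = max_sr) {
  dat <- tibble::tibble(
    max_i = dplyr::pull(df, {{ max_i }}),
    max_sr = dplyr::pull(df, {{ max_sr }})
  )
  if (nrow(dat) < 3) stop("need at least 3 contrast points", call. = FALSE)
  if (stats::sd(dat$max_i) == 0) {
    stop("zero variance in the Doppler maxima", call. = FALSE)
  }
  fit <- stats::lm(max_sr ~ max_i, data = dat)
  sst <- sum((dat$max_sr - mean(dat$max_sr))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else NA_real_
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n = nrow(dat), fit = fit, data = dat
    ),
    class = "amp_calibration"
  )
}

#' @export
print.amp_calibration <- function(x, ...) {
  cat(sprintf(
    "<amp_calibration> slope %.3g %%dSR per %%dI (intercept %.3g, R2 %.3f, n=%d)\n",
    x$slope, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}

#' Compare spatial response profiles after peak alignment
#'
#' Shifts the spike-rate depth profile by an integer number of bins so its
#' maximum coincides with the Doppler profile's, computes the Pearson
#' correlation on the overlapping support, and the FWHM difference
#' `FWHM(dI) - FWHM(dSR)` in mm (positive = spatially wider hemodynamic
#' response).
#'
#' @param sr_profile,i_profile Per-bin response amplitudes along the same
#'   trajectory (e.g. per-bin maxima during the stimulus window).
#' @param pitch_mm Bin pitch in mm (default 0.1).
#' @param interpolate Passed to [fwhm()].
#' @return One-row tibble: `r`, `dfwhm_mm`, `shift_bins`, `fwhm_i_mm`,
#'   `fwhm_sr_mm`.
#' @export
spatial_compare <- function(sr_profile, i_profile, pitch_mm = 0.1,
                            interpolate = FALSE) {
  stopifnot(length(sr_profile) == length(i_profile))
  if (max(sr_profile) <= 0 || max(i_profile) <= 0) {
    stop("profile without positive peak", call. = FALSE)
  }
  shift <- which.max(i_profile) - which.max(sr_profile)
  n <- length(sr_profile)
  src <- seq_len(n) - shift
  ok <- src >= 1 & src <= n
  r <- stats::cor(i_profile[ok], sr_profile[src[ok]])
  tibble::tibble(
    r = r,
    dfwhm_mm = fwhm(i_profile, pitch_mm, interpolate) -
      fwhm(sr_profile, pitch_mm, interpolate),
    shift_bins = shift,
    fwhm_i_mm = fwhm(i_profile, pitch_mm, interpolate),
    fwhm_sr_mm = fwhm(sr_profile, pitch_mm, interpolate)
  )
}

#' Recover the spatial coupling width from matched depth profiles
#'
#' Least-squares fit of the forward model's spatial kernel: finds the
#' Gaussian SD sigma (mm) such that the spike-rate profile convolved with
#' the unit-sum discretized kernel best predicts the Doppler profile up to
#' an affine gain (`i ~ a * blur(sr, sigma) + b`).
#'
#' @param sr_profile,i_profile Depth profiles along the trajectory.
#' @param pitch_mm Bin pitch in mm.
#' @param interval Search interval for sigma in mm.
#' @param max_shift Residual integer bin misalignments up to this size are
#'   absorbed by a joint shift search (0 disables).
#' @return List of class `spatial_fit`: `sigma_mm`, `gain`, `offset`,
#'   `shift_bins`, `mse`.
#' @export
fit_spatial_sigma <- function(sr_profile, i_profile, pitch_mm = 0.1,
                              interval = c(1e-3, 1), max_shift = 3) {
  stopifnot(length(sr_profile) == length(i_profile))
  n <- length(sr_profile)
  overlap <- function(shift) {
    src <- seq_len(n) - shift
    ok <- src >= 1 & src <= n
    list(i = which(ok), sr = src[ok])
  }
  mse_at <- function(sigma, shift) {
    m <- centered_conv(sr_profile, gaussian_taps(sigma / pitch_mm))
    ov <- overlap(shift)
    mean(stats::resid(stats::lm(i_profile[ov$i] ~ m[ov$sr]))^2)
  }
  best <- NULL
  for (shift in -max_shift:max_shift) {
    opt <- stats::optimize(mse_at, interval = interval, shift = shift)
    if (is.null(best) || opt$objective < best$mse) {
      best <- list(sigma = opt$minimum, shift = shift, mse = opt$objective)
    }
  }
  m <- centered_conv(sr_profile, gaussian_taps(best$sigma / pitch_mm))
  ov <- overlap(best$shift)
  fit <- stats::lm(i_profile[ov$i] ~ m[ov$sr])
  structure(
    list(
      sigma_mm = best$sigma,
      gain = unname(stats::coef(fit)[2]),
      offset = unname(stats::coef(fit)[1]),
      shift_bins = best$shift,
      mse = best$mse
    ),
    class = "spatial_fit"
  )
}

#' Compare a metric across regions
#'
#' Uncorrected group comparisons as used for between-region contrasts:
#' pairwise two-sided independent-samples t-tests, or a single
#' Kruskal-Wallis test across all groups.
#'
#' @param df Data frame with one row per observation.
#' @param value,group Value and grouping columns (tidy-evaluated).
#' @param test `"t"` (pairwise) or `"kruskal"` (omnibus).
#' @return A tibble with `statistic` and `p_value` (one row per pair for
#'   `"t"`, one row for `"kruskal"`).
#' @export
group_compare <- function(df, value, group, test = c("t", "kruskal")) {
  test <- match.arg(test)
  v <- dplyr::pull(df, {{ value }})
  g <- as.character(dplyr::pull(df, {{ group }}))
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  if (test == "kruskal") {
    kt <- stats::kruskal.test(v, factor(g))
    return(tibble::tibble(
      test = "kruskal", group1 = NA_character_, group2 = NA_character_,
      statistic = unname(kt$statistic), p_value = kt$p.value
    ))
  }
  pairs <- utils::combn(sort(unique(g)), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- v[g == pairs[1, i]]
    b <- v[g == pairs[2, i]]
    tt <- stats::t.test(a, b)
    tibble::tibble(
      test = "t", group1 = pairs[1, i], group2 = pairs[2, i],
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
}

#' Per-bin spatial response profiles along a trajectory
#'
#' Temporal reduction of the matched signals for spatial comparison: for
#' each depth bin, the trial-averaged percent-change trace is reduced over
#' the stimulus window. Doppler values are read as the mean of the lateral
#' band of `band` voxels on each side of the trajectory voxel (the same
#' strip the region traces use); spike values at the matching depth bins.
#'
#' `reduce = "max"` is the maximum amplitude during stimulus presentation.
#' `reduce = "mean"` is the stimulus-window mean: a linear reduction that
#' commutes with the spatial convolution, so the Doppler profile is exactly
#' the Gaussian-blurred spike profile in expectation -- preferred when
#' recovering the spatial kernel width with [fit_spatial_sigma()].
#'
#' @param session A `fus_session`.
#' @param trajectory A [probe_trajectory()] (default the session's).
#' @param contrast Contrast condition (default the highest).
#' @param reduce Temporal reduction, `"max"` or `"mean"`.
#' @param band Lateral half-width (voxels) of the Doppler read-out strip.
#' @return Tibble `bin`, `row`, `col`, `sr`, `i` (% change amplitudes).
#' @export
spatial_profiles <- function(session, trajectory = NULL, contrast = NULL,
                             reduce = c("max", "mean"), band = 3) {
  reduce <- match.arg(reduce)
  if (is.null(trajectory)) trajectory <- session$trajectory
  tl <- session$timeline
  gd <- dim(session$mask)
  if (is.null(contrast)) contrast <- max(session$trials$contrast)
  tv <- trajectory_voxels(trajectory, gd)
  N <- min(nrow(tv), dim(session$spikes)[1])
  ids <- session$trials$trial[session$trials$contrast == contrast]

  # band voxels per bin (clipped at the grid edge)
  offs <- -band:band
  cols <- outer(tv$col[seq_len(N)], offs, "+")
  ok <- cols >= 1 & cols <= gd[2]
  lin <- (cols - 1L) * gd[1] + tv$row[seq_len(N)]
  grp <- row(lin)[ok]
  lin <- lin[ok]
  stride <- gd[1] * gd[2]
  nT <- dim(session$doppler)[4]
  idx <- as.vector(outer(lin, (seq_len(tl$n_frames * nT) - 1L) * stride, "+"))
  vox <- session$doppler[idx]
  dim(vox) <- c(length(lin), tl$n_frames * nT)
  traces <- rowsum(vox, grp) / as.vector(table(grp))
  dim(traces) <- c(N, tl$n_frames, nT)

  di <- matrix(0, N, tl$n_frames)
  dsr <- matrix(0, N, tl$n_frames)
  for (i in ids) {
    di <- di + delta_rows(traces[, , i], tl$baseline_frames)
    dsr <- dsr + delta_rows(
      session$spikes[seq_len(N), , i] / tl$frame_s, tl$baseline_frames
    )
  }
  di <- di / length(ids)
  dsr <- dsr / length(ids)
  win <- tl$stim_frames
  red <- if (reduce == "max") {
    function(m) apply(m, 1, max)
  } else {
    function(m) rowMeans(m)
  }
  tibble::tibble(
    bin = seq_len(N), row = tv$row[seq_len(N)], col = tv$col[seq_len(N)],
    sr = red(dsr[, win, drop = FALSE]),
    i = red(di[, win, drop = FALSE])
  )
}
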
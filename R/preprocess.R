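#' Percent change from baseline
#'
#' Converts a raw per-frame trace (Doppler intensity or spike rate) to
#' percent change relative to its pre-stimulus baseline mean:
#' `100 * (x - basal) / basal`, with `basal` the mean over the frames from
#' trial start to stimulus onset.
#'
#' @param x Numeric trace, one value per frame.
#' @param timeline A [trial_timeline()] defining the baseline window.
#' @return Numeric trace of percent changes. If the baseline mean is zero
#'   the trace is invalid: all-`NA` is returned with a warning so it can be
#'   excluded downstream.
#' @export
#' @examples
#' tl <- trial_timeline(5, 1, 1, 1)
#' compute_delta(c(rep(10, 5), rep(12, 10)), tl) # 0s then 20s
compute_delta <- function(x, timeline) {
  stopifnot(length(x) == timeline$n_frames)
  basal <- mean(x[timeline$baseline_frames])
  if (!is.finite(basal) || basal == 0) {
    warning("baseline mean is zero; trace flagged invalid (all NA)",
      call. = FALSE
    )
    return(rep(NA_real_, length(x)))
  }
  100 * (x - basal) / basal
}

# rows = traces (voxels/bins), cols = frames; per-row baseline
delta_rows <- function(m, baseline_frames) {
  basal <- rowMeans(m[, baseline_frames, drop = FALSE])
  d <- 100 * (m / basal - 1)
  d[basal == 0 | !is.finite(basal), ] <- NA_real_
  d
}

#' Trial-averaged percent-change Doppler movie
#'
#' Computes the per-trial percent-change movie (per-voxel, per-trial
#' baseline) and averages it across the trials of each requested contrast.
#'
#' @param session A `fus_session` (or any list with `doppler`, `trials`,
#'   `timeline` of the same layout).
#' @param contrasts Contrast conditions to average (default: all present).
#' @return Named list (one element per contrast) of arrays
#'   `[row, col, frame]` of mean percent change.
#' @export
delta_movie_average <- function(session, contrasts = NULL) {
  tl <- session$timeline
  d <- dim(session$doppler)
  nvox <- d[1] * d[2]
  if (is.null(contrasts)) contrasts <- sort(unique(session$trials$contrast))
  out <- lapply(contrasts, function(cc) {
    ids <- session$trials$trial[session$trials$contrast == cc]
    acc <- matrix(0, nvox, d[3])
    for (i in ids) {
      m <- session$doppler[, , , i]
      dim(m) <- c(nvox, d[3])
      acc <- acc + delta_rows(m, tl$baseline_frames)
    }
    acc <- acc / length(ids)
    dim(acc) <- c(d[1], d[2], d[3])
    acc
  })
  stats::setNames(out, as.character(contrasts))
}

#' Pointwise trial average with 95% confidence band
#'
#' @param x Matrix of traces, frames in rows, trials in columns.
#' @param conf Confidence level (default 0.95); the band is the Student-t
#'   interval across trials at each frame.
#' @return A tibble with `frame`, `mean`, `sd`, `ci_lo`, `ci_hi`, `n`.
#'   With a single trial the band is reported absent (`NA`).
#' @export
trial_average <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  n <- ncol(x)
  mu <- rowMeans(x)
  if (n >= 2) {
    s <- apply(x, 1, stats::sd)
    hw <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  } else {
    s <- rep(NA_real_, nrow(x))
    hw <- rep(NA_real_, nrow(x))
  }
  tibble::tibble(
    frame = seq_len(nrow(x)), mean = mu, sd = s,
    ci_lo = mu - hw, ci_hi = mu + hw, n = n
  )
}

#' Two-step normalization of contrast-maximum curves
#'
#' Each session's curve of per-contrast response maxima is first z-scored
#' across its contrast conditions (removing inter-session and inter-region
#' scale), then all pooled values are affinely rescaled to \[0, 1\].
#'
#' @param df A data frame with one row per (curve, contrast).
#' @param value Column of curve values (tidy-evaluated).
#' @param ... Grouping columns identifying a curve (e.g. session, region,
#'   modality).
#' @return The input tibble plus `z` (per-curve z-score) and `norm` (pooled
#'   \[0, 1\] rescale). Curves with zero variance across contrasts are
#'   dropped with a warning.
#' @export
normalize_curve_max <- function(df, value, ...) {
  df <- dplyr::group_by(df, ...)
  if (any(dplyr::group_size(df) < 2)) {
    stop("each curve needs at least 2 contrast values", call. = FALSE)
  }
  df <- dplyr::mutate(df,
    .curve_sd = stats::sd({{ value }}),
    z = ({{ value }} - mean({{ value }})) / .curve_sd
  )
  df <- dplyr::ungroup(df)
  if (any(df$.curve_sd == 0)) {
    warning("dropping constant curve(s) (zero variance across contrasts)",
      call. = FALSE
    )
    df <- dplyr::filter(df, .curve_sd > 0)
    if (nrow(df) == 0) stop("no curves left after dropping", call. = FALSE)
  }
  rng <- range(df$z)
  dplyr::mutate(dplyr::select(df, -".curve_sd"),
    norm = (z - rng[1]) / (rng[2] - rng[1])
  )
}

#' Voxelwise stimulus correlation map
#'
#' Squared Pearson correlation between each voxel's percent-change trace and
#' a stimulus regressor (default: the boxcar over stimulus frames).
#'
#' @param delta Array `[row, col, frame]` of percent change (e.g. one
#'   element of [delta_movie_average()]).
#' @param timeline A [trial_timeline()]; used for the default regressor.
#' @param regressor Optional numeric regressor (length = frame count), e.g.
#'   the boxcar convolved with a fitted kernel,
#'   `causal_conv(stimulus_boxcar(tl), sample_gamma_kernel(gp))`, for a
#'   hemodynamically delayed reference. The map is sign-blind:
#'   anti-correlated voxels score as high as correlated ones.
#' @return A tibble `row`, `col`, `r2` (in \[0, 1\]; zero-variance voxels
#'   report 0).
#' @export
correlation_map <- function(delta, timeline = NULL, regressor = NULL) {
  d <- dim(delta)
  stopifnot(length(d) == 3)
  if (is.null(regressor)) {
    stopifnot(!is.null(timeline))
    regressor <- stimulus_boxcar(timeline)
  }
  stopifnot(length(regressor) == d[3])
  m <- delta
  dim(m) <- c(d[1] * d[2], d[3])
  rc <- regressor - mean(regressor)
  mc <- m - rowMeans(m)
  num <- as.vector(mc %*% rc)
  den2 <- rowSums(mc^2) * sum(rc^2)
  r2 <- ifelse(den2 > 0, num^2 / den2, 0)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    r2 = r2
  )
}

#' Bin raw spike times into the fUS resolution
#'
#' Sums spikes over groups of `n_contacts_per_bin` adjacent contacts
#' (5 x 20 um = one 100-um depth bin) and over half-open 0.2-s windows
#' `[t, t + bin_s)`; spikes at an exact edge fall in the later bin. A
#' trailing group of fewer than `n_contacts_per_bin` contacts is dropped
#' with a warning.
#'
#' @param spike_times Data frame with columns `contact` (1-based, ordered
#'   by depth, tip first), `time_s`, and optionally `trial`.
#' @param n_contacts Total number of contacts (contacts without spikes
#'   still count towards binning).
#' @param n_contacts_per_bin Contacts per depth bin (default 5).
#' @param timeline A [trial_timeline()]; time bins are `[0, bin_s)`, ...
#'   up to the trial length.
#' @param output `"counts"` (default) or `"rate"` (counts / bin_s, spikes/s).
#' @return Array `[depth_bin, time_bin, trial]` with attribute `bin_s`.
#' @export
bin_spikes <- function(spike_times, n_contacts,
                       n_contacts_per_bin = 5, timeline = trial_timeline(),
                       output = c("counts", "rate")) {
  output <- match.arg(output)
  bin_s <- timeline$frame_s
  trial_len <- timeline$baseline_s + timeline$stim_s + timeline$post_s
  stopifnot(all(spike_times$contact >= 1 & spike_times$contact <= n_contacts))
  if (any(spike_times$time_s < 0 | spike_times$time_s >= trial_len)) {
    stop("spike times must lie within [0, trial length)", call. = FALSE)
  }
  n_bins <- n_contacts %/% n_contacts_per_bin
  if (n_bins == 0) stop("fewer contacts than one depth bin", call. = FALSE)
  if (n_contacts %% n_contacts_per_bin != 0) {
    warning(sprintf(
      "dropping trailing group of %d contact(s) (not a full bin)",
      n_contacts %% n_contacts_per_bin
    ), call. = FALSE)
  }
  if (!"trial" %in% names(spike_times)) spike_times$trial <- 1L
  trials <- sort(unique(spike_times$trial))
  if (length(trials) == 0) trials <- 1L # no spikes: one all-zero trial
  depth <- (spike_times$contact - 1L) %/% n_contacts_per_bin + 1L
  tbin <- floor(spike_times$time_s / bin_s) + 1L
  keep <- depth <= n_bins
  counts <- table(
    factor(depth[keep], levels = seq_len(n_bins)),
    factor(tbin[keep], levels = seq_len(timeline$n_frames)),
    factor(spike_times$trial[keep], levels = trials)
  )
  out <- array(as.numeric(counts),
    dim = c(n_bins, timeline$n_frames, length(trials))
  )
  if (output == "rate") out <- out / bin_s
  attr(out, "bin_s") <- bin_s
  out
}

#' Baseline firing-rate estimate
#'
#' Mean spike count over the pre-stimulus baseline window divided by the
#' bin duration, averaged over depth bins and trials.
#'
#' @param spikes Array `[bin, frame, trial]` of counts (e.g.
#'   `session$spikes`).
#' @param timeline A [trial_timeline()].
#' @return Estimated basal rate in spikes/s.
#' @export
baseline_rate <- function(spikes, timeline) {
  mean(spikes[, timeline$baseline_frames, , drop = FALSE]) / timeline$frame_s
}

#' Session inclusion filter
#'
#' Keeps a session iff (a) at the highest contrast the stimulus-window mean
#' exceeds the baseline mean across trials (one-sided paired t-test at
#' `alpha`) for both modalities, and (b) at least one trajectory bin lies in
#' the target region.
#'
#' @param session A `fus_session`.
#' @param trajectory Trajectory to evaluate (default: the session's).
#' @param region_id Region label to test against (default 1).
#' @param alpha Significance level (default 0.05).
#' @param band Lateral band half-width (voxels) for the fUS region trace.
#' @return A one-row tibble: `keep`, `crosses_region`, `p_fus`, `p_spikes`,
#'   `reason` (`NA` if kept).
#' @export
include_session <- function(session, trajectory = NULL, region_id = 1L,
                            alpha = 0.05, band = 3) {
  if (is.null(trajectory)) trajectory <- session$trajectory
  tl <- session$timeline
  tv <- trajectory_voxels(trajectory, dim(session$mask))
  crosses <- any(session$mask[cbind(tv$row, tv$col)] == region_id)
  if (!crosses) {
    return(tibble::tibble(
      keep = FALSE, crosses_region = FALSE,
      p_fus = NA_real_, p_spikes = NA_real_,
      reason = "trajectory does not cross the target region"
    ))
  }
  cmax <- max(session$trials$contrast)
  onesided <- function(signal) {
    tr <- region_average(session, trajectory,
      signal = signal, region_id = region_id,
      band = band, contrasts = cmax, per_trial = TRUE
    )
    wide <- tidyr::pivot_wider(tr,
      id_cols = "frame", names_from = "trial", values_from = "value"
    )
    m <- as.matrix(wide[, -1, drop = FALSE])
    stim <- colMeans(m[tl$stim_frames, , drop = FALSE])
    base <- colMeans(m[tl$baseline_frames, , drop = FALSE])
    ok <- is.finite(stim) & is.finite(base)
    if (sum(ok) < 2 || stats::sd(stim[ok] - base[ok]) == 0) {
      return(NA_real_)
    }
    stats::t.test(stim[ok], base[ok],
      paired = TRUE, alternative = "greater"
    )$p.value
  }
  p_fus <- onesided("doppler")
  p_spk <- onesided("spikes")
  sig <- isTRUE(p_fus < alpha) && isTRUE(p_spk < alpha)
  tibble::tibble(
    keep = sig, crosses_region = TRUE, p_fus = p_fus, p_spikes = p_spk,
    reason = if (sig) {
      NA_character_
    } else {
      "no significant response at the highest contrast in both modalities"
    }
  )
}
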
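#' Per-contrast response maxima
#'
#' Reduces trial-averaged region traces to one maximum per contrast over
#' the post-onset window (every frame from stimulus onset to trial end, so
#' delayed hemodynamic peaks are captured; restrict via `window`).
#'
#' @param traces Tibble from [region_average()] (`contrast`, `frame`,
#'   `value`).
#' @param timeline A [trial_timeline()].
#' @param window `"post_onset"` (default) or `"stimulus"`.
#' @return Tibble `contrast`, `max_value`.
#' @export
contrast_maxima <- function(traces, timeline,
                            window = c("post_onset", "stimulus")) {
  window <- match.arg(window)
  frames <- if (window == "post_onset") {
    seq(timeline$onset_frame, timeline$n_frames)
  } else {
    timeline$stim_frames
  }
  traces |>
    dplyr::filter(.data$frame %in% frames) |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(max_value = max(.data$value), .groups = "drop")
}

#' Run the full coupling analysis on one session
#'
#' Orchestrates the per-session pipeline: Monte-Carlo probe alignment,
#' trajectory-based region averaging, session inclusion test, per-contrast
#' maxima and the amplitude-calibration regression, ridge transfer-function
#' estimation with gamma parameterization, and the spatial-spread
#' comparison at the highest contrast.
#'
#' @param session A `fus_session`.
#' @param initial Initial trajectory estimate (defaults to the session's
#'   stored trajectory; for synthetic recovery pass a perturbed one).
#' @param n_candidates Monte-Carlo candidates for alignment.
#' @param seed Seed for candidate sampling.
#' @param lag Transfer-function lag window in frames.
#' @param lambda Ridge penalty policy (see [fit_tf()]).
#' @param band Lateral band half-width for region averaging.
#' @param align Run the Monte-Carlo alignment (if `FALSE` the initial
#'   trajectory is used as-is).
#' @return Object of class `session_pipeline`: list with `result` (one-row
#'   tibble of derived metrics), `alignment`, `traces` (list `sr`, `i`),
#'   `maxima`, `amp`, `tf`, `gamma_fit`, `profiles`, `spatial`,
#'   `inclusion`.
#' @export
run_session_pipeline <- function(session, initial = NULL,
                                 n_candidates = 10000, seed = 1,
                                 lag = 20, lambda = "cv", band = 3,
                                 align = TRUE) {
  tl <- session$timeline
  if (is.null(initial)) initial <- session$trajectory

  alignment <- if (align) {
    align_probe(session, initial, n_candidates = n_candidates, seed = seed)
  } else {
    list(trajectory = initial, score = NA_real_)
  }
  traj <- alignment$trajectory

  inclusion <- include_session(session, traj, band = band)

  sr <- region_average(session, traj, signal = "spikes", band = band)
  di <- region_average(session, traj, signal = "doppler", band = band)

  mx <- dplyr::inner_join(
    dplyr::rename(contrast_maxima(di, tl), max_i = "max_value"),
    dplyr::rename(contrast_maxima(sr, tl), max_sr = "max_value"),
    by = "contrast"
  )
  amp <- amplitude_regression(mx)

  tf <- estimate_tf(sr, di, lag = lag, lambda = lambda, step_s = tl$frame_s)
  tfm <- tf_metrics(tf)
  gfit <- tryCatch(fit_gamma(tf), error = function(e) NULL)

  profiles <- spatial_profiles(session, traj, band = band)
  spat <- tryCatch(
    spatial_compare(profiles$sr, profiles$i, pitch_mm = 0.1),
    error = function(e) {
      tibble::tibble(
        r = NA_real_, dfwhm_mm = NA_real_, shift_bins = NA_integer_,
        fwhm_i_mm = NA_real_, fwhm_sr_mm = NA_real_
      )
    }
  )
  prof_mean <- spatial_profiles(session, traj, reduce = "mean", band = band)
  sigma <- tryCatch(
    fit_spatial_sigma(prof_mean$sr, prof_mean$i, pitch_mm = 0.1)$sigma_mm,
    error = function(e) NA_real_
  )

  result <- tibble::tibble(
    region = session$config$region$name,
    keep = inclusion$keep,
    align_score = alignment$score,
    tip_col = traj$tip_col, tip_row = traj$tip_row, slope_traj = traj$slope,
    slope = amp$slope, intercept = amp$intercept, r2_amp = amp$r_squared,
    tf_time_to_peak_s = tfm$time_to_peak_s, tf_fwhm_s = tfm$fwhm_s,
    tf_lambda = tf$lambda, tf_r_squared = tf$r_squared,
    sigma_mm = sigma,
    spatial_r = spat$r, spatial_dfwhm_mm = spat$dfwhm_mm
  )
  structure(
    list(
      result = result, alignment = alignment,
      traces = list(sr = sr, i = di), maxima = mx, amp = amp,
      tf = tf, gamma_fit = gfit, profiles = profiles, spatial = spat,
      inclusion = inclusion
    ),
    class = "session_pipeline"
  )
}

#' @export
print.session_pipeline <- function(x, ...) {
  cat("<session_pipeline>\n")
  print(x$result)
  invisible(x)
}

#' Parameter-recovery study over seeded synthetic sessions
#'
#' Generates `n_sessions` independent synthetic sessions for one region
#' configuration, runs the full pipeline on each (alignment starts from a
#' deliberately perturbed copy of the true trajectory, emulating a B-mode
#' estimate), and returns one row of recovered metrics per session together
#' with the generator truths.
#'
#' @param region A [region_config()].
#' @param n_sessions Number of sessions (seeds).
#' @param seed Master seed; per-session seeds are drawn from it.
#' @param n_trials Trials per contrast (default 20).
#' @param grid_dim Voxel grid (default a probe-centered 143 x 32 field of
#'   view).
#' @param noise_sd Doppler noise SD (% dI).
#' @param contrasts Contrast conditions.
#' @param n_candidates Alignment candidates per session.
#' @param init_offset Perturbation `c(d_col, d_row, d_slope)` applied to
#'   the true trajectory to form the initial alignment estimate.
#' @param ... Further arguments to [session_config()].
#' @return Tibble with one row per session: recovered metrics (see
#'   [run_session_pipeline()]) plus `session`, `seed_session`,
#'   `true_slope`, `true_ttp_s`, `true_sigma_mm`, `tip_err_vox`.
#' @export
recovery_study <- function(region = sc_config(), n_sessions = 20, seed = 1,
                           n_trials = 20, grid_dim = c(143, 32),
                           noise_sd = 5,
                           contrasts = c(0, 5, 10, 30, 50, 100),
                           n_candidates = 10000,
                           init_offset = c(2, -2, 0.08), ...) {
  seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, n_sessions)
  )
  purrr::map_dfr(seq_len(n_sessions), function(i) {
    cfg <- session_config(
      region = region, grid_dim = grid_dim, contrasts = contrasts,
      n_trials = n_trials, noise_sd = noise_sd, ...
    )
    s <- gen_session(cfg, seeds[i])
    init <- probe_trajectory(
      s$trajectory$tip_col + init_offset[1],
      s$trajectory$tip_row + init_offset[2],
      s$trajectory$slope + init_offset[3],
      s$trajectory$n_bins
    )
    pl <- run_session_pipeline(s,
      initial = init,
      n_candidates = n_candidates, seed = seeds[i]
    )
    res <- pl$result
    res$session <- i
    res$seed_session <- seeds[i]
    res$true_slope <- region$slope_amp
    res$true_ttp_s <- gamma_peak_time(region$gamma)
    res$true_sigma_mm <- cfg$sigma_mm
    res$tip_err_vox <- max(
      abs(res$tip_col - s$trajectory$tip_col),
      abs(res$tip_row - s$trajectory$tip_row)
    )
    rm(s, pl)
    gc(verbose = FALSE)
    res
  })
}

#' Aggregate study results by region
#'
#' Mean, SD, median and quartiles (linear-interpolation convention) of
#' each recovered metric, one row per region x metric. With a single
#' session the SD is reported missing, not zero.
#'
#' @param results Tibble from [recovery_study()] (possibly row-bound across
#'   regions).
#' @param metrics Character vector of metric columns to summarize.
#' @return Tibble `region`, `metric`, `n`, `mean`, `sd`, `q1`, `median`,
#'   `q3`.
#' @export
study_report <- function(results,
                         metrics = c(
                           "slope", "r2_amp", "tf_time_to_peak_s",
                           "tf_fwhm_s", "sigma_mm", "spatial_r",
                           "spatial_dfwhm_mm"
                         )) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  results |>
    dplyr::select("region", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-"region",
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$region, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() >= 2) stats::sd(.data$value) else NA_real_,
      q1 = stats::quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = stats::median(.data$value),
      q3 = stats::quantile(.data$value, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    )
}
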
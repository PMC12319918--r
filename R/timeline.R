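#' Trial timeline
#'
#' Describes the temporal layout of a single trial: a pre-stimulus baseline,
#' a stimulus window, and a post-stimulus window, imaged at a fixed frame
#' rate. The default (5 Hz, 10 s / 4 s / 20 s) yields 170 frames per 34-s
#' trial, matching a flickering-checkerboard contrast session.
#'
#' @param frame_rate_hz Imaging frame rate in frames per second.
#' @param baseline_s Seconds of baseline before stimulus onset.
#' @param stim_s Stimulus duration in seconds.
#' @param post_s Seconds after stimulus offset.
#'
#' @return An object of class `trial_timeline`: a list with the inputs plus
#'   `n_frames`, `frame_s` (frame step in seconds), `baseline_frames`,
#'   `stim_frames`, `post_frames` (1-based frame indices) and `onset_frame`
#'   (first stimulus frame).
#' @export
#' @examples
#' tl <- trial_timeline()
#' tl$n_frames # 170
trial_timeline <- function(frame_rate_hz = 5, baseline_s = 10, stim_s = 4,
                           post_s = 20) {
  stopifnot(is.numeric(frame_rate_hz), frame_rate_hz > 0)
  if (baseline_s <= 0 || stim_s <= 0 || post_s <= 0) {
    stop("all trial durations must be > 0", call. = FALSE)
  }
  n_frames <- round(frame_rate_hz * (baseline_s + stim_s + post_s))
  n_base <- round(frame_rate_hz * baseline_s)
  n_stim <- round(frame_rate_hz * stim_s)
  structure(
    list(
      frame_rate_hz = frame_rate_hz,
      baseline_s = baseline_s, stim_s = stim_s, post_s = post_s,
      frame_s = 1 / frame_rate_hz,
      n_frames = n_frames,
      baseline_frames = seq_len(n_base),
      stim_frames = seq(n_base + 1L, n_base + n_stim),
      post_frames = seq(n_base + n_stim + 1L, n_frames),
      onset_frame = n_base + 1L
    ),
    class = "trial_timeline"
  )
}

#' @export
print.trial_timeline <- function(x, ...) {
  cat(sprintf(
    "<trial_timeline> %g Hz, %g + %g + %g s (%d frames)\n",
    x$frame_rate_hz, x$baseline_s, x$stim_s, x$post_s, x$n_frames
  ))
  invisible(x)
}

#' Frame times of a timeline
#'
#' @param timeline A [trial_timeline()].
#' @param relative_to `"trial"` for times from trial start, `"onset"` for
#'   times relative to stimulus onset.
#' @return Numeric vector of frame times in seconds (frame centers are not
#'   used; frame k starts at (k-1) * frame_s).
#' @export
frame_times <- function(timeline, relative_to = c("trial", "onset")) {
  relative_to <- match.arg(relative_to)
  t0 <- (seq_len(timeline$n_frames) - 1) * timeline$frame_s
  if (relative_to == "onset") t0 <- t0 - timeline$baseline_s
  t0
}

#' Boxcar stimulus regressor
#'
#' 1 during stimulus frames, 0 elsewhere; the default regressor for
#' voxelwise correlation maps.
#'
#' @param timeline A [trial_timeline()].
#' @return Numeric vector of length `timeline$n_frames`.
#' @export
stimulus_boxcar <- function(timeline) {
  out <- numeric(timeline$n_frames)
  out[timeline$stim_frames] <- 1
  out
}
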
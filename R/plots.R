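#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an estimated transfer function
#'
#' Coefficients against lag time, with the fitted gamma kernel overlaid
#' when supplied.
#'
#' @param object A `transfer_function`.
#' @param gamma_fit Optional `gamma_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transfer_function <- function(object, gamma_fit = NULL, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lag_s, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(
      x = "lag (s)", y = "coefficient",
      title = "Estimated temporal transfer function"
    )
  if (!is.null(gamma_fit)) {
    ts <- seq(0, max(d$lag_s), length.out = 200)
    gd <- tibble::tibble(
      lag_s = ts,
      estimate = gamma_kernel(ts, gamma_fit$params)
    )
    p <- p + ggplot2::geom_line(
      data = gd, colour = "orange", linewidth = 0.8
    )
  }
  p
}

#' Plot an amplitude calibration
#'
#' Per-contrast response maxima of the two modalities with the fitted
#' calibration line.
#'
#' @param object An `amp_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amp_calibration <- function(object, ...) {
  ggplot2::ggplot(
    object$data, ggplot2::aes(x = .data$max_i, y = .data$max_sr)
  ) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "red"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "max ΔI (%)", y = "max ΔSR (%)",
      title = sprintf(
        "Amplitude calibration: slope %.1f, R² %.2f",
        object$slope, object$r_squared
      )
    )
}

#' Plot a voxelwise correlation map
#'
#' @param map Tibble from [correlation_map()].
#' @param trajectory Optional [probe_trajectory()] overlaid as points.
#' @return A ggplot (raster of r-squared; rows increase downwards as in the
#'   image).
#' @export
plot_correlation_map <- function(map, trajectory = NULL) {
  p <- ggplot2::ggplot(
    map, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$r2)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "lateral (voxels)", y = "depth (voxels)",
      fill = "r²"
    )
  if (!is.null(trajectory)) {
    tv <- trajectory_voxels(trajectory)
    p <- p + ggplot2::geom_point(
      data = tv, ggplot2::aes(x = .data$col, y = .data$row),
      inherit.aes = FALSE, colour = "red", size = 0.5
    )
  }
  p
}

#' Plot trial-averaged region traces per contrast
#'
#' @param traces Tibble from [region_average()].
#' @param timeline A [trial_timeline()]; marks the stimulus window.
#' @return A ggplot of % change against time, one line per contrast.
#' @export
plot_region_traces <- function(traces, timeline = NULL) {
  p <- ggplot2::ggplot(traces, ggplot2::aes(
    x = .data$time_s, y = .data$value,
    colour = factor(.data$contrast)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "Δ (%)", colour = "contrast (%)"
    )
  if (!is.null(timeline)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = timeline$baseline_s,
      xmax = timeline$baseline_s + timeline$stim_s,
      ymin = -Inf, ymax = Inf, alpha = 0.12
    )
  }
  p
}

#' Plot matched spatial profiles along the probe
#'
#' @param profiles Tibble from [spatial_profiles()].
#' @param pitch_mm Depth bin pitch in mm.
#' @return A ggplot of peak-normalized profiles against depth.
#' @export
plot_spatial_profiles <- function(profiles, pitch_mm = 0.1) {
  d <- tidyr::pivot_longer(
    dplyr::mutate(profiles,
      depth_mm = (.data$bin - 1) * pitch_mm,
      sr = .data$sr / max(.data$sr), i = .data$i / max(.data$i)
    ),
    c("sr", "i"),
    names_to = "modality", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$depth_mm, y = .data$value, colour = .data$modality
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(sr = "black", i = "red"),
      labels = c(sr = "ΔSR", i = "ΔI")
    ) +
    ggplot2::labs(
      x = "distance from tip (mm)", y = "normalized amplitude",
      colour = NULL
    )
}
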
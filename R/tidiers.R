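#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transfer function
#'
#' @param x A `transfer_function`.
#' @param ... Unused.
#' @return Tibble `lag`, `lag_s`, `estimate`.
#' @export
tidy.transfer_function <- function(x, ...) {
  tibble::tibble(
    lag = seq_along(x$coeffs) - 1L,
    lag_s = x$lag_s,
    estimate = unname(x$coeffs)
  )
}

#' @rdname tidy.transfer_function
#' @return For `glance`: one row with `lambda`, `r_squared`, `n_obs`,
#'   `time_to_peak_s`, `fwhm_s`.
#' @export
glance.transfer_function <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      lambda = x$lambda, r_squared = x$r_squared, n_obs = x$n_obs
    ),
    tf_metrics(x)[, c("time_to_peak_s", "fwhm_s")]
  )
}

#' Tidy a fitted gamma parameterization
#'
#' @param x A `gamma_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` for amplitude, shape, scale and
#'   delay.
#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "shape", "scale_s", "delay_s"),
    estimate = c(
      x$params$amplitude, x$params$shape,
      x$params$scale_s, x$params$delay_s
    )
  )
}

#' @rdname tidy.gamma_fit
#' @export
glance.gamma_fit <- function(x, ...) {
  tibble::tibble(
    residual_rms = x$residual_rms,
    converged = x$converged,
    peak_s = gamma_peak_time(x$params),
    fwhm_s = gamma_fwhm(x$params)
  )
}

#' Tidy an amplitude calibration
#'
#' @param x An `amp_calibration`.
#' @param ... Unused.
#' @return Coefficient table (term, estimate, std.error, statistic,
#'   p.value).
#' @export
tidy.amp_calibration <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname tidy.amp_calibration
#' @export
glance.amp_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n = x$n
  )
}

#' Tidy a probe alignment
#'
#' @param x A `probe_alignment`.
#' @param ... Unused.
#' @return The candidate tibble with perturbations and scores.
#' @export
tidy.probe_alignment <- function(x, ...) {
  x$candidates
}

#' @rdname tidy.probe_alignment
#' @export
glance.probe_alignment <- function(x, ...) {
  tibble::tibble(
    tip_col = x$trajectory$tip_col, tip_row = x$trajectory$tip_row,
    slope = x$trajectory$slope, score = x$score,
    n_candidates = nrow(x$candidates), contrast = x$contrast
  )
}
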
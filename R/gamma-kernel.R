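#' Gamma kernel parameters
#'
#' Parameterization of the temporal neurovascular transfer kernel
#' Gamma(t) = a * ((t - d)/tau)^(k-1) * exp(-(t - d)/tau) for t > d, 0
#' otherwise, normalized so its peak value is `amplitude`. The kernel peaks
#' at t = d + (k - 1) * tau.
#'
#' @param amplitude Peak value `a` (kernel is scaled to this maximum).
#' @param shape Shape `k` (> 1 so the kernel rises from zero).
#' @param scale_s Scale `tau` in seconds (> 0).
#' @param delay_s Onset delay `d` in seconds (>= 0).
#' @return An object of class `gamma_params`.
#' @export
#' @examples
#' gp <- gamma_params(shape = 3, scale_s = 0.4)
#' gamma_peak_time(gp) # 0.8 s
gamma_params <- function(amplitude = 1, shape, scale_s, delay_s = 0) {
  stopifnot(is.numeric(shape), is.numeric(scale_s), is.numeric(delay_s))
  if (shape <= 1) stop("gamma shape must be > 1", call. = FALSE)
  if (scale_s <= 0) stop("gamma scale must be > 0", call. = FALSE)
  if (delay_s < 0) stop("gamma delay must be >= 0", call. = FALSE)
  structure(
    list(
      amplitude = amplitude, shape = shape,
      scale_s = scale_s, delay_s = delay_s
    ),
    class = "gamma_params"
  )
}

#' @export
print.gamma_params <- function(x, ...) {
  cat(sprintf(
    "<gamma_params> a=%.3g k=%.3g tau=%.3g s d=%.3g s (peak %.3g s)\n",
    x$amplitude, x$shape, x$scale_s, x$delay_s, gamma_peak_time(x)
  ))
  invisible(x)
}

#' Evaluate a gamma kernel
#'
#' @param t_s Times in seconds (vectorized).
#' @param params A [gamma_params()].
#' @return Kernel values; 0 for `t_s < delay_s`, peak equals `amplitude`.
#' @export
gamma_kernel <- function(t_s, params) {
  stopifnot(inherits(params, "gamma_params"))
  k <- params$shape
  u <- (t_s - params$delay_s) / params$scale_s
  # log-space relative to the mode (u = k - 1) for numerical stability
  lpeak <- (k - 1) * log(k - 1) - (k - 1)
  out <- ifelse(u > 0, exp((k - 1) * log(pmax(u, 1e-300)) - u - lpeak), 0)
  params$amplitude * out
}

#' Analytic peak time of a gamma kernel
#'
#' @param params A [gamma_params()].
#' @return `delay_s + (shape - 1) * scale_s`, in seconds.
#' @export
gamma_peak_time <- function(params) {
  params$delay_s + (params$shape - 1) * params$scale_s
}

#' Continuous full width at half maximum of a gamma kernel
#'
#' Width between the two half-peak crossings of the continuous kernel
#' (not the discrete longest-run measure used on sampled signals).
#'
#' @param params A [gamma_params()].
#' @return FWHM in seconds.
#' @export
gamma_fwhm <- function(params) {
  tp <- gamma_peak_time(params)
  f <- function(t) gamma_kernel(t, params) - params$amplitude / 2
  # bracket the rising crossing where the normalized kernel is surely < 1/2:
  # (u/(k-1))^(k-1) * e^(k-1) = 1e-3 (rise term only, e^-u ~ 1)
  k <- params$shape
  u_lo <- max((k - 1) * 1e-3^(1 / (k - 1)) / exp(1), 1e-300)
  t_lo <- params$delay_s + params$scale_s * u_lo
  if (f(t_lo) >= 0) {
    stop("kernel too close to exponential for a half-max rise point",
      call. = FALSE
    )
  }
  lo <- stats::uniroot(f, c(t_lo, tp))$root
  hi <- stats::uniroot(f, c(tp, tp + 50 * params$scale_s * sqrt(k)))$root
  hi - lo
}

#' Solve the gamma shape for a target FWHM at fixed peak time
#'
#' Finds `shape` (and the implied `scale_s = (peak_s - delay_s)/(shape - 1)`)
#' such that the continuous kernel FWHM equals `fwhm_s`. Wider kernels at a
#' fixed peak need a smaller shape.
#'
#' @param fwhm_s Target continuous FWHM in seconds.
#' @param peak_s Target peak time in seconds.
#' @param delay_s Onset delay in seconds (default 0).
#' @return A [gamma_params()] with amplitude 1.
#' @export
gamma_params_for_fwhm <- function(fwhm_s, peak_s, delay_s = 0) {
  stopifnot(fwhm_s > 0, peak_s > delay_s)
  obj <- function(k) {
    gp <- gamma_params(1, k, (peak_s - delay_s) / (k - 1), delay_s)
    gamma_fwhm(gp) - fwhm_s
  }
  k <- stats::uniroot(obj, c(1.2, 200))$root
  gamma_params(1, k, (peak_s - delay_s) / (k - 1), delay_s)
}

#' Sample a gamma kernel on the frame grid
#'
#' @param params A [gamma_params()].
#' @param step_s Sample step in seconds (default 0.2, the 5-Hz frame step).
#' @param n_taps Number of samples (lags 0 .. n_taps-1). Default covers the
#'   kernel support: lags up to `delay_s + 12 * scale_s * shape`.
#' @return Numeric vector of kernel samples at t = 0, step_s, ...
#' @export
sample_gamma_kernel <- function(params, step_s = 0.2, n_taps = NULL) {
  if (is.null(n_taps)) {
    t_max <- params$delay_s + params$scale_s * (params$shape - 1) +
      10 * params$scale_s * sqrt(params$shape)
    n_taps <- max(2L, ceiling(t_max / step_s) + 1L)
  }
  gamma_kernel((seq_len(n_taps) - 1) * step_s, params)
}
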
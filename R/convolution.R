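# Discretized kernels and causal convolution shared by the synthetic
# generator and the forward model, so the two agree tap-for-tap.

#' Discretized Gaussian kernel
#'
#' Samples a Gaussian at integer offsets `-radius .. radius` and normalizes
#' to unit sum (so convolution preserves total mass). `sigma_px = 0` returns
#' the identity kernel.
#'
#' @param sigma_px Gaussian SD in sample units (pixels/bins).
#' @param radius Half-width in samples; default `ceiling(4 * sigma_px)`.
#' @return Numeric vector of length `2 * radius + 1` summing to 1, with
#'   attribute `offsets`.
#' @export
gaussian_taps <- function(sigma_px, radius = NULL) {
  if (sigma_px < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma_px == 0) {
    return(structure(1, offsets = 0L))
  }
  if (is.null(radius)) radius <- ceiling(4 * sigma_px)
  off <- seq(-radius, radius)
  w <- exp(-off^2 / (2 * sigma_px^2))
  structure(w / sum(w), offsets = as.integer(off))
}

#' Causal convolution with zero-padded past
#'
#' `y[t] = sum_j taps[j + 1] * x[t - j]`, with `x` taken as 0 before its
#' first sample. Output has the same length as `x`.
#'
#' @param x Numeric vector (or matrix with time in rows; columns are
#'   convolved independently).
#' @param taps Kernel taps at lags 0, 1, 2, ...
#' @return Same shape as `x`.
#' @export
causal_conv <- function(x, taps) {
  nt <- length(taps)
  if (is.matrix(x)) {
    pad <- matrix(0, nt - 1L, ncol(x))
    y <- stats::filter(rbind(pad, x), taps, method = "convolution", sides = 1)
    y <- as.matrix(y)[nt:(nt - 1L + nrow(x)), , drop = FALSE]
    dimnames(y) <- dimnames(x)
    y
  } else {
    y <- stats::filter(c(rep(0, nt - 1L), x), taps,
      method = "convolution", sides = 1
    )
    as.numeric(y)[nt:(nt - 1L + length(x))]
  }
}

# symmetric (centered) convolution with zero padding, same length as x
centered_conv <- function(x, taps) {
  off <- attr(taps, "offsets")
  if (is.null(off)) off <- seq_along(taps) - (length(taps) + 1L) %/% 2L
  n <- length(x)
  y <- numeric(n)
  for (j in seq_along(taps)) {
    src <- seq_len(n) - off[j]
    ok <- src >= 1 & src <= n
    y[ok] <- y[ok] + taps[j] * x[src[ok]]
  }
  y
}
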
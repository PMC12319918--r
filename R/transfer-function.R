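#' Lag-stacked design matrix for transfer-function estimation
#'
#' For each frame t with a full lag window, a row holds the percent
#' spike-rate change at lags 0..`lag` (column j multiplies dSR(t - j + 1)),
#' and the response entry is the percent Doppler change at t. Rows are
#' stacked across all contrast conditions.
#'
#' @param sr_traces,i_traces Tibbles as returned by [region_average()]
#'   (columns `contrast`, `frame`, `value`), time-aligned at the same frame
#'   rate, or plain numeric vectors for a single condition.
#' @param lag Number of past frames in the window (default 20, i.e. 21 taps
#'   spanning 4 s at 0.2 s/frame).
#' @return List with `X` (rows x (lag+1) matrix, columns `lag0`, `lag1`,
#'   ...), `y`, `lag`, and `group` (contrast id per row, for
#'   leave-one-contrast-out cross-validation).
#' @export
build_design <- function(sr_traces, i_traces, lag = 20) {
  as_trace_list <- function(x) {
    if (is.numeric(x)) {
      return(list(`1` = as.numeric(x)))
    }
    split(x$value[order(x$contrast, x$frame)],
      sort(x$contrast),
      drop = TRUE
    )
  }
  xs <- as_trace_list(sr_traces)
  ys <- as_trace_list(i_traces)
  stopifnot(identical(names(xs), names(ys)))
  parts <- purrr::map2(xs, ys, function(x, y) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < lag + 1) {
      stop("trace shorter than the lag window + 1", call. = FALSE)
    }
    t_idx <- seq(lag + 1L, n)
    X <- vapply(0:lag, function(j) x[t_idx - j], numeric(length(t_idx)))
    list(X = X, y = y[t_idx])
  })
  X <- do.call(rbind, purrr::map(parts, "X"))
  colnames(X) <- paste0("lag", 0:lag)
  list(
    X = X,
    y = unlist(purrr::map(parts, "y"), use.names = FALSE),
    lag = lag,
    group = rep(names(xs), times = purrr::map_int(parts, ~ length(.x$y)))
  )
}

# centered ridge solve; lambda penalizes slopes only, intercept free
ridge_solve <- function(X, y, lambda) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc) + diag(lambda, ncol(X))
  beta <- tryCatch(
    solve(A, crossprod(Xc, y - ym)),
    error = function(e) {
      if (lambda == 0) {
        stop("design is singular with lambda = 0; use lambda > 0",
          call. = FALSE
        )
      }
      stop(e)
    }
  )
  beta <- as.vector(beta)
  list(beta = beta, intercept = ym - sum(xm * beta))
}

#' Fit the temporal transfer function by ridge regression
#'
#' Minimizes `||y - X beta - b0||^2 + lambda ||beta||^2` (intercept
#' unpenalized). Coefficient j is the weight of the spike-rate change j
#' frames in the past (causal lag order). `lambda = "cv"` selects the
#' penalty by leave-one-contrast-out cross-validation over a log-spaced
#' grid.
#'
#' @param design A list from [build_design()] (or `X`,`y` supplied
#'   directly via `X = , y = `).
#' @param lambda `"cv"` (default), or a fixed non-negative penalty.
#' @param lambda_grid Candidate penalties for cross-validation.
#' @param step_s Frame step in seconds (for lag times; default 0.2).
#' @param X,y Design matrix and response, as an alternative to `design`.
#' @return Object of class `transfer_function`: `coeffs` (lag 0..L),
#'   `lag_s`, `intercept`, `lambda`, `cv` (tibble of CV error per lambda,
#'   or `NULL`), `r_squared` (training), `n_obs`.
#' @export
fit_tf <- function(design = NULL, lambda = "cv",
                   lambda_grid = 10^seq(-4, 4, length.out = 17),
                   step_s = 0.2, X = NULL, y = NULL) {
  if (is.null(design)) design <- list(X = X, y = y, group = NULL)
  X <- design$X
  y <- design$y
  stopifnot(is.matrix(X), length(y) == nrow(X))
  cv_tbl <- NULL
  if (identical(lambda, "cv")) {
    grp <- design$group
    folds <- if (!is.null(grp) && length(unique(grp)) >= 2) {
      split(seq_along(y), grp)
    } else {
      split(seq_along(y), rep_len(1:5, length(y)))
    }
    err <- vapply(lambda_grid, function(lm) {
      sum(vapply(folds, function(idx) {
        fit <- ridge_solve(X[-idx, , drop = FALSE], y[-idx], lm)
        sum((y[idx] - X[idx, , drop = FALSE] %*% fit$beta -
          fit$intercept)^2)
      }, numeric(1)))
    }, numeric(1))
    cv_tbl <- tibble::tibble(lambda = lambda_grid, press = err)
    lambda <- lambda_grid[which.min(err)]
  }
  stopifnot(is.numeric(lambda), lambda >= 0)
  fit <- ridge_solve(X, y, lambda)
  pred <- as.vector(X %*% fit$beta + fit$intercept)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  structure(
    list(
      coeffs = stats::setNames(fit$beta, colnames(X)),
      lag_s = (seq_len(ncol(X)) - 1) * step_s,
      intercept = fit$intercept, lambda = lambda,
      cv = cv_tbl, r_squared = r2, n_obs = length(y), step_s = step_s
    ),
    class = "transfer_function"
  )
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf(
    "<transfer_function> %d taps (0-%g s), lambda = %.3g, R2 = %.3f\n",
    length(x$coeffs), max(x$lag_s), x$lambda, x$r_squared
  ))
  invisible(x)
}

#' Summary metrics of an estimated transfer function
#'
#' Time-to-peak (first occurrence of the coefficient maximum, in seconds)
#' and FWHM (longest run of coefficients strictly above half the peak,
#' times the frame step). The global-maximum reading of time-to-peak is
#' used because the model kernel is unimodal and sample-level local maxima
#' of ridge coefficients are noise-dominated.
#'
#' @param tf A `transfer_function`.
#' @return One-row tibble: `time_to_peak_s`, `fwhm_s`, `peak_value`.
#' @export
tf_metrics <- function(tf) {
  co <- unname(tf$coeffs)
  tibble::tibble(
    time_to_peak_s = time_to_peak(co,
      onset_frame = 1, step_s = tf$step_s,
      mode = "global"
    ),
    fwhm_s = fwhm(co, step = tf$step_s),
    peak_value = max(co)
  )
}

#' Fit a gamma parameterization to transfer-function coefficients
#'
#' Least-squares fit of `a * ((t - d)/tau)^(k-1) * exp(-(t - d)/tau)`
#' (0 for `t < d`, unit-peak normalized times `a`) to the estimated taps,
#' via Levenberg-Marquardt with box constraints (k > 1, tau > 0, d >= 0).
#'
#' @param tf A `transfer_function`, or a numeric vector of taps.
#' @param step_s Frame step (ignored when `tf` is a `transfer_function`).
#' @return Object of class `gamma_fit`: `params` ([gamma_params()]),
#'   `fitted`, `residual_rms`, `converged`.
#' @export
fit_gamma <- function(tf, step_s = 0.2) {
  co <- if (inherits(tf, "transfer_function")) {
    step_s <- tf$step_s
    unname(tf$coeffs)
  } else {
    as.numeric(tf)
  }
  if (max(co) <= 0) {
    stop("transfer function has no positive peak", call. = FALSE)
  }
  t_s <- (seq_along(co) - 1) * step_s
  if (stats::sd(co) == 0) stop("flat transfer function", call. = FALSE)
  peak_i <- which.max(co)
  tp0 <- max(t_s[peak_i], step_s)
  fw0 <- tryCatch(fwhm(co, step_s), error = function(e) 2 * step_s)
  start_k <- tryCatch(
    gamma_params_for_fwhm(fw0, tp0)$shape,
    error = function(e) 3
  )
  # tolerant kernel for the optimizer: finite-difference steps may probe
  # just outside the box constraints
  gk <- function(t, k, tau, d) {
    k <- pmax(k, 1 + 1e-9)
    tau <- pmax(tau, 1e-9)
    u <- (t - d) / tau
    lpeak <- (k - 1) * log(k - 1) - (k - 1)
    ifelse(u > 0, exp((k - 1) * log(pmax(u, 1e-300)) - u - lpeak), 0)
  }
  fit <- minpack.lm::nls.lm(
    par = c(a = max(co), k = start_k, tau = tp0 / (start_k - 1), d = 0),
    lower = c(a = 0, k = 1 + 1e-6, tau = 1e-6, d = 0),
    upper = c(a = Inf, k = 200, tau = Inf, d = max(t_s)),
    fn = function(p) co - p[["a"]] * gk(t_s, p[["k"]], p[["tau"]], p[["d"]]),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$info %in% 1:4) {
    stop("gamma fit did not converge: ", fit$message, call. = FALSE)
  }
  est <- fit$par
  fitted <- est[["a"]] * gk(t_s, est[["k"]], est[["tau"]], est[["d"]])
  structure(
    list(
      params = gamma_params(
        est[["a"]], max(est[["k"]], 1 + 1e-6),
        max(est[["tau"]], 1e-6), max(est[["d"]], 0)
      ),
      fitted = fitted,
      residual_rms = sqrt(mean((co - fitted)^2)),
      converged = fit$info %in% 1:3,
      step_s = step_s
    ),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("<gamma_fit> RMS residual", signif(x$residual_rms, 3), "\n")
  print(x$params)
  invisible(x)
}

#' Spatiotemporal forward model
#'
#' Predicts the percent Doppler change field from a percent spike-rate
#' change field over (depth bins x frames): spatial convolution along depth
#' with a unit-sum discretized Gaussian (sigma in mm at the bin pitch),
#' then causal temporal convolution with the gamma kernel sampled at the
#' frame step. `sigma_mm = 0` with a unit-impulse kernel is the identity.
#'
#' @param sr_field Matrix `[depth_bin, frame]` of dSR (%).
#' @param sigma_mm Spatial Gaussian SD in mm (>= 0).
#' @param gamma A [gamma_params()] temporal kernel, or a numeric vector of
#'   kernel taps at the frame step.
#' @param pitch_mm Depth bin pitch in mm (default 0.1).
#' @param step_s Frame step in seconds (default 0.2).
#' @return Matrix of predicted dI (%) with the shape of `sr_field`.
#' @export
forward_model <- function(sr_field, sigma_mm, gamma,
                          pitch_mm = 0.1, step_s = 0.2) {
  stopifnot(is.matrix(sr_field))
  if (sigma_mm < 0) stop("sigma must be >= 0", call. = FALSE)
  taps <- if (inherits(gamma, "gamma_params")) {
    sample_gamma_kernel(gamma, step_s = step_s)
  } else {
    as.numeric(gamma)
  }
  g <- gaussian_taps(sigma_mm / pitch_mm)
  blurred <- apply(sr_field, 2, centered_conv, taps = g)
  if (!is.matrix(blurred)) blurred <- matrix(blurred, nrow = 1)
  t(causal_conv(t(blurred), taps))
}

#' Predict the Doppler trace from a spike-rate trace and score the fit
#'
#' Causal convolution of the percent spike-rate change with the estimated
#' transfer-function taps (plus intercept), compared against the observed
#' percent Doppler change.
#'
#' @param tf A `transfer_function`.
#' @param sr_trace,i_trace Numeric traces at the same frame rate.
#' @return List with `predicted` and `r_squared` (coefficient of
#'   determination, floored at 0).
#' @export
predict_and_score <- function(tf, sr_trace, i_trace) {
  stopifnot(inherits(tf, "transfer_function"))
  if (length(sr_trace) != length(i_trace)) {
    stop("trace length mismatch", call. = FALSE)
  }
  pred <- causal_conv(sr_trace, unname(tf$coeffs)) + tf$intercept
  sst <- sum((i_trace - mean(i_trace))^2)
  r2 <- if (sst > 0) 1 - sum((i_trace - pred)^2) / sst else 0
  list(predicted = pred, r_squared = max(0, r2))
}

#' Estimate the transfer function from region-averaged traces
#'
#' Convenience wrapper: builds the lag-stacked design from per-contrast
#' trial-averaged traces and fits the ridge transfer function.
#'
#' @inheritParams build_design
#' @inheritParams fit_tf
#' @param ... Further arguments passed to [fit_tf()].
#' @return A `transfer_function`.
#' @export
estimate_tf <- function(sr_traces, i_traces, lag = 20, lambda = "cv",
                        step_s = 0.2, ...) {
  fit_tf(build_design(sr_traces, i_traces, lag = lag),
    lambda = lambda, step_s = step_s, ...
  )
}
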
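test_that("lag-stacked design has the documented shape and ordering", {
  x <- seq_len(170)
  y <- rev(x)
  d <- build_design(x, y, lag = 20)
  expect_equal(dim(d$X), c(150, 21))
  expect_equal(d$y, y[21:170])
  # column j holds the trace j - 1 frames in the past
  expect_equal(d$X[1, ], setNames(rev(x[1:21]), paste0("lag", 0:20)))
  # stacking across contrasts multiplies the rows
  tr <- tibble::tibble(
    contrast = rep(c(0, 5, 10, 30, 50, 100), each = 170),
    frame = rep(1:170, 6), value = rnorm(6 * 170)
  )
  d6 <- build_design(tr, tr, lag = 20)
  expect_equal(nrow(d6$X), 900)
  expect_equal(as.integer(table(d6$group)), rep(150L, 6))
  expect_error(build_design(rnorm(15), rnorm(15), lag = 20), "shorter")
})

test_that("noiseless known-kernel deconvolution recovers every tap", {
  withr::with_seed(8, {
    kern <- gamma_kernel((0:20) * 0.2, gamma_params(0.05, 3, 0.4))
    x <- rnorm(400)
    y <- causal_conv(x, kern)
    tf <- fit_tf(build_design(x, y, lag = 20), lambda = 1e-8)
    expect_lt(max(abs(unname(tf$coeffs) - kern)), 1e-6)
  })
})

test_that("ridge at lambda = 0 equals ordinary least squares", {
  withr::with_seed(15, {
    X <- matrix(rnorm(200 * 8), 200, 8)
    y <- rnorm(200)
    tf <- fit_tf(X = X, y = y, lambda = 0, step_s = 0.2)
    ols <- lm(y ~ X)
    expect_lt(max(abs(unname(tf$coeffs) - unname(coef(ols)[-1]))), 1e-8)
    expect_lt(abs(tf$intercept - coef(ols)[1]), 1e-8)
  })
})

test_that("ridge degenerates sensibly: zero response, infinite penalty, rank", {
  withr::with_seed(16, {
    x <- rnorm(300)
    d <- build_design(x, rep(0, 300), lag = 10)
    expect_lt(max(abs(fit_tf(d, lambda = 1)$coeffs)), 1e-12)
    y <- causal_conv(x, c(1, 0.5))
    d2 <- build_design(x, y, lag = 10)
    expect_lt(max(abs(fit_tf(d2, lambda = 1e12)$coeffs)), 1e-4)
    # constant regressor: singular at lambda = 0
    dc <- build_design(rep(1, 100), rnorm(100), lag = 10)
    expect_error(fit_tf(dc, lambda = 0), "lambda > 0")
  })
})

test_that("cross-validated penalty tracks the noise level", {
  withr::with_seed(17, {
    kern <- gamma_kernel((0:20) * 0.2, gamma_params(0.1, 3, 0.4))
    tr <- tibble::tibble(
      contrast = rep(c(0, 50, 100), each = 170), frame = rep(1:170, 3),
      value = rnorm(510)
    )
    ytr <- dplyr::mutate(tr,
      value = causal_conv(value, kern) + rnorm(510, sd = 0.02)
    )
    tf <- fit_tf(build_design(tr, ytr, lag = 20), lambda = "cv")
    expect_s3_class(tf$cv, "tbl_df")
    expect_equal(tf$lambda, tf$cv$lambda[which.min(tf$cv$press)])
    expect_lt(max(abs(unname(tf$coeffs) - kern)), 0.05)
  })
})

test_that("gamma fit recovers parameters from exactly sampled taps", {
  gp <- gamma_params(1, 3, 0.4, 0)
  taps <- gamma_kernel((0:20) * 0.2, gp)
  gf <- fit_gamma(taps)
  expect_true(gf$converged)
  expect_equal(gf$params$amplitude, 1, tolerance = 0.01)
  expect_equal(gf$params$shape, 3, tolerance = 0.01)
  expect_equal(gf$params$scale_s, 0.4, tolerance = 0.01)
  expect_equal(gamma_peak_time(gf$params), 0.8, tolerance = 0.01)
  expect_lt(gf$residual_rms, 1e-6)
  expect_error(fit_gamma(rep(0.5, 21)), "flat")
  expect_error(fit_gamma(-gamma_kernel((0:20) * 0.2, gp)), "positive")
})

test_that("forward model reduces to the identity with identity kernels", {
  withr::with_seed(20, {
    sr <- matrix(rnorm(30 * 60), 30, 60)
    out <- forward_model(sr, sigma_mm = 0, gamma = c(1))
    expect_equal(out, sr)
    expect_equal(forward_model(sr * 0, 0.15, gamma_params(1, 3, 0.4)),
      sr * 0,
      ignore_attr = TRUE
    )
  })
})

test_that("forward model is linear and translation-equivariant in depth", {
  gp <- gamma_params(1, 3, 0.4)
  withr::with_seed(21, {
    a <- matrix(rnorm(40 * 50), 40, 50)
    b <- matrix(rnorm(40 * 50), 40, 50)
    f <- function(m) forward_model(m, 0.15, gp)
    expect_lt(
      max(abs(f(2 * a + 3 * b) - (2 * f(a) + 3 * f(b)))),
      1e-10 * max(abs(f(a)))
    )
  })
  # impulse responses at interior depths are shifted copies
  imp <- function(at) {
    m <- matrix(0, 40, 10)
    m[at, 1] <- 1
    forward_model(m, 0.15, gp)
  }
  r1 <- imp(15)
  r2 <- imp(25)
  expect_equal(r1[10:20, ], r2[20:30, ], tolerance = 1e-12)
})

test_that("spatial impulse response has the closed-form Gaussian FWHM", {
  m <- matrix(0, 41, 3)
  m[21, 1] <- 1
  out <- forward_model(m, sigma_mm = 0.15, gamma = c(1))
  w <- fwhm(out[, 1], step = 0.1)
  expect_lt(abs(w - 2.3548 * 0.15), 0.1) # within one 0.1-mm bin
})

test_that("prediction scores are exact on self-generated data and floored", {
  withr::with_seed(22, {
    kern <- gamma_kernel((0:20) * 0.2, gamma_params(0.05, 3, 0.4))
    x <- rnorm(300)
    y <- causal_conv(x, kern)
    tf <- fit_tf(build_design(x, y, lag = 20), lambda = 1e-8)
    ps <- predict_and_score(tf, x, y)
    expect_equal(ps$r_squared, 1, tolerance = 1e-9)
    tf0 <- tf
    tf0$coeffs[] <- 0
    tf0$intercept <- 0
    expect_equal(predict_and_score(tf0, x, y)$r_squared, 0)
    expect_error(predict_and_score(tf, x, y[-1]), "mismatch")
  })
})

test_that("prediction quality degrades monotonically with noise", {
  withr::with_seed(23, {
    kern <- gamma_kernel((0:20) * 0.2, gamma_params(0.1, 3, 0.4))
    x <- rnorm(500)
    clean <- causal_conv(x, kern)
    r2 <- sapply(c(0.05, 0.3, 1), function(sd) {
      mean(replicate(10, {
        y <- clean + rnorm(500, sd = sd)
        tf <- fit_tf(build_design(x, y, lag = 20), lambda = 1e-6)
        predict_and_score(tf, x, y)$r_squared
      }))
    })
    expect_true(all(diff(r2) < 0))
  })
})
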
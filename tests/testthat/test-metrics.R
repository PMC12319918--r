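test_that("time to peak finds the first peak after onset", {
  # peak 4 frames after onset at 5 Hz
  x <- c(rep(0, 10), 0.2, 0.5, 0.8, 1.5, 1.0, 0.3, rep(0, 4))
  expect_equal(time_to_peak(x, onset_frame = 11, step_s = 0.2), 0.6)
  # impulse at onset
  expect_equal(time_to_peak(c(0, 0, 1, 0, 0), 3, 0.2), 0)
  # two equal maxima: the earlier wins
  expect_equal(time_to_peak(c(0, 1, 0, 1, 0), 1, 0.2), 0.2)
  # plateau counts from its first sample
  expect_equal(time_to_peak(c(0, 2, 2, 1), 1, 0.2), 0.2)
  # monotone rise has no peak
  expect_true(is.na(time_to_peak(1:10, 2, 0.2)))
  # global mode returns the first occurrence of the maximum
  expect_equal(
    time_to_peak(c(0, 1, 0, 2, 2, 0), 1, 0.2, mode = "global"), 0.6
  )
})

test_that("FWHM counts the longest run strictly above half peak", {
  # rectangular pulse of 8 frames
  x <- c(rep(0, 5), rep(1, 8), rep(0, 5))
  expect_equal(fwhm(x, step = 0.2), 1.6)
  # single-sample spike
  expect_equal(fwhm(c(0, 0, 1, 0), step = 0.2), 0.2)
  # split runs: the longest counts
  expect_equal(fwhm(c(1, 0, 1, 1, 0.4, 1, 1, 1), step = 1), 3)
  expect_error(fwhm(c(0, 0, 0), 1), "positive")
  expect_error(fwhm(c(-1, -2), 1), "positive")
})

test_that("FWHM is invariant to positive rescaling", {
  withr::with_seed(30, {
    x <- abs(rnorm(50)) + dnorm(seq(-3, 3, length.out = 50)) * 10
    for (k in c(0.2, 7, 1e3)) {
      expect_equal(fwhm(k * x, 0.2), fwhm(x, 0.2))
    }
  })
})

test_that("interpolated FWHM matches the continuous Gaussian width", {
  xs <- seq(-3, 3, by = 0.1)
  g <- exp(-xs^2 / (2 * 0.5^2))
  expect_equal(fwhm(g, step = 0.1, interpolate = TRUE),
    2.3548 * 0.5,
    tolerance = 0.01
  )
})

test_that("outlier rule drops values above mean + 2 sd, computed literally", {
  a <- c(1.0, 1.1, 0.9, 5.0)
  expect_equal(remove_outliers(a), a[a <= mean(a) + 2 * sd(a)])
  b <- c(1, 1, 1, 9)
  expect_equal(remove_outliers(b), b[b <= mean(b) + 2 * sd(b)])
  # literal application: 9 < 3 + 2*4 = 11, so it is kept
  expect_true(9 %in% remove_outliers(b))
  expect_equal(remove_outliers(c(1, 1, 1, 1e6)), c(1, 1, 1, 1e6)[
    c(1, 1, 1, 1e6) <= mean(c(1, 1, 1, 1e6)) + 2 * sd(c(1, 1, 1, 1e6))
  ])
})

test_that("amplitude regression is exact on a noiseless line", {
  d <- tibble::tibble(max_i = c(0, 1, 2, 5, 8, 10))
  d$max_sr <- 7.7 * d$max_i
  ar <- amplitude_regression(d)
  expect_equal(ar$slope, 7.7, tolerance = 1e-12)
  expect_equal(ar$intercept, 0, tolerance = 1e-9)
  expect_equal(ar$r_squared, 1, tolerance = 1e-12)
  expect_error(amplitude_regression(d[1:2, ]), "3 contrast")
  expect_error(
    amplitude_regression(tibble::tibble(max_i = c(1, 1, 1), max_sr = 1:3)),
    "variance"
  )
})

test_that("null regression R2 over 6 points averages 1/(n - 1) = 0.2", {
  withr::with_seed(33, {
    r2 <- replicate(1000, {
      amplitude_regression(
        tibble::tibble(max_i = rnorm(6), max_sr = rnorm(6))
      )$r_squared
    })
  })
  expect_equal(mean(r2), 0.2, tolerance = 0.15)
})

test_that("calibration slope is equivariant to axis rescaling", {
  withr::with_seed(34, {
    d <- tibble::tibble(max_i = runif(6, 0, 10))
    d$max_sr <- 21.4 * d$max_i + rnorm(6)
    s1 <- amplitude_regression(d)$slope
    d2 <- dplyr::mutate(d, max_i = max_i * 4)
    expect_equal(amplitude_regression(d2)$slope, s1 / 4, tolerance = 1e-12)
  })
})

test_that("spatial comparison aligns peaks and signs the width difference", {
  prof <- exp(-(seq_len(41) - 21)^2 / (2 * 4^2))
  same <- spatial_compare(prof, prof)
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_equal(same$dfwhm_mm, 0)
  # smoothing widens: positive difference means wider Doppler extent
  blurred <- centered_conv(prof, gaussian_taps(2.5))
  out <- spatial_compare(prof, blurred)
  expect_gt(out$dfwhm_mm, 0)
  # a shifted copy re-aligns to r = 1
  shifted <- c(rep(0, 5), prof[1:36])
  out2 <- spatial_compare(prof, shifted)
  expect_equal(out2$shift_bins, 5)
  expect_equal(out2$r, 1, tolerance = 1e-9)
  expect_error(spatial_compare(-prof, prof), "positive")
})

test_that("Gaussian convolution widens by the closed-form amount", {
  # FWHM 1.0 mm profile blurred with sigma 0.15 mm:
  # sqrt(1 + (2.3548 * 0.15)^2) - 1 = 0.0607 mm, resolvable only with
  # sub-sample interpolation
  sig_mm <- 1.0 / 2.3548
  prof <- exp(-((seq_len(61) - 31) * 0.1)^2 / (2 * sig_mm^2))
  blurred <- centered_conv(prof, gaussian_taps(1.5))
  out <- spatial_compare(prof, blurred, pitch_mm = 0.1, interpolate = TRUE)
  expect_equal(out$dfwhm_mm, sqrt(1 + (2.3548 * 0.15)^2) - 1,
    tolerance = 0.05
  )
})

test_that("spatial sigma fit recovers the kernel width from clean profiles", {
  prof <- exp(-(seq_len(41) - 21)^2 / (2 * 4^2))
  blurred <- centered_conv(prof, gaussian_taps(1.5)) # sigma 0.15 mm
  fit <- fit_spatial_sigma(prof, 3 * blurred + 0.5, pitch_mm = 0.1)
  expect_equal(fit$sigma_mm, 0.15, tolerance = 0.01)
  expect_equal(fit$gain, 3, tolerance = 0.01)
  expect_equal(fit$shift_bins, 0)
  # a one-bin misalignment is absorbed by the shift search
  fit2 <- fit_spatial_sigma(prof, c(blurred[-1], 0), pitch_mm = 0.1)
  expect_equal(fit2$sigma_mm, 0.15, tolerance = 0.015)
})

test_that("group comparisons behave at the degenerate anchors", {
  d_same <- tibble::tibble(
    value = rep(c(1, 2, 3), 2), region = rep(c("SC", "LGN"), each = 3)
  )
  tt <- group_compare(d_same, value, region, test = "t")
  expect_equal(tt$p_value, 1, tolerance = 1e-9)
  d3 <- tibble::tibble(
    value = rep(c(1, 2, 3), 3), region = rep(c("SC", "LGN", "V1"), each = 3)
  )
  kw <- group_compare(d3, value, region, test = "kruskal")
  expect_equal(kw$statistic, 0, tolerance = 1e-9)
  expect_error(
    group_compare(d_same[1:4, ], value, region), ">= 2 groups"
  )
  expect_error(
    group_compare(d_same[1:3, ], value, region), ">= 2 groups"
  )
})

test_that("separated groups are detected with high power", {
  withr::with_seed(35, {
    p <- replicate(30, {
      d <- tibble::tibble(
        value = c(rnorm(20), rnorm(20, mean = 5)),
        region = rep(c("A", "B"), each = 20)
      )
      group_compare(d, value, region, test = "t")$p_value
    })
  })
  expect_gt(mean(p < 0.001), 0.99)
})
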
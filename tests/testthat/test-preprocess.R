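tl60 <- trial_timeline(5, 4, 2, 6) # 60 frames, onset at frame 21

test_that("percent change follows the baseline-relative formula", {
  expect_equal(compute_delta(rep(3.7, 60), tl60), rep(0, 60))
  x <- c(rep(10, 20), rep(12, 40))
  expect_equal(compute_delta(x, tl60)[21], 20)
  expect_warning(
    d <- compute_delta(c(rep(0, 20), rep(1, 40)), tl60),
    "invalid"
  )
  expect_true(all(is.na(d)))
})

test_that("percent change is invariant to the scale of the raw trace", {
  withr::with_seed(1, {
    for (k in c(0.01, 3, 1e4)) {
      x <- abs(rnorm(60, mean = 50, sd = 5))
      expect_lt(
        max(abs(compute_delta(k * x, tl60) - compute_delta(x, tl60))),
        1e-9
      )
    }
  })
})

test_that("trial averages and confidence bands behave as expected", {
  m <- matrix(rep(c(1, 2, 3), 4), nrow = 3) # identical trials
  ta <- trial_average(m)
  expect_equal(ta$mean, c(1, 2, 3))
  expect_equal(ta$ci_hi - ta$ci_lo, rep(0, 3))
  ta2 <- trial_average(cbind(c(0, 2), c(2, 0)))
  expect_equal(ta2$mean, c(1, 1))
  # single trial: band absent, not zero
  ta1 <- trial_average(matrix(1:3, ncol = 1))
  expect_true(all(is.na(ta1$ci_lo)))
})

test_that("confidence band shrinks as 1/sqrt(n) when trials double", {
  withr::with_seed(99, {
    hw <- sapply(c(50, 100), function(n) {
      mean(replicate(60, {
        ta <- trial_average(matrix(rnorm(20 * n), 20, n))
        mean(ta$ci_hi - ta$ci_lo)
      }))
    })
    ratio_expected <- (qt(0.975, 49) / sqrt(50)) / (qt(0.975, 99) / sqrt(100))
    expect_equal(hw[1] / hw[2], ratio_expected, tolerance = 0.1)
  })
})

test_that("curve-max normalization z-scores per curve then pools to [0, 1]", {
  d <- tibble::tibble(
    session = 1, contrast = c(0, 5, 10, 30, 50, 100),
    max_value = c(1, 2, 3, 4, 5, 6)
  )
  out <- normalize_curve_max(d, max_value, session)
  expect_equal(out$norm, seq(0, 1, by = 0.2))
  # multiple curves: pooled range is exactly [0, 1]
  d2 <- dplyr::bind_rows(
    d,
    tibble::tibble(
      session = 2, contrast = d$contrast,
      max_value = c(2, 2.5, 7, 8, 20, 21)
    )
  )
  out2 <- normalize_curve_max(d2, max_value, session)
  expect_equal(range(out2$norm), c(0, 1))
  # identical curves normalize identically
  d3 <- dplyr::bind_rows(d, dplyr::mutate(d, session = 2))
  out3 <- normalize_curve_max(d3, max_value, session)
  expect_equal(out3$norm[1:6], out3$norm[7:12])
})

test_that("curve-max normalization is idempotent on normalized curves", {
  d <- tibble::tibble(
    session = rep(1:2, each = 6), contrast = rep(c(0, 5, 10, 30, 50, 100), 2),
    max_value = c(1, 2, 3, 5, 8, 9, 0.5, 0.7, 2, 2.5, 4, 4.1)
  )
  once <- normalize_curve_max(d, max_value, session)
  twice <- normalize_curve_max(
    dplyr::select(once, session, contrast, max_value = norm),
    max_value, session
  )
  expect_equal(twice$norm, once$norm, tolerance = 1e-12)
})

test_that("constant curves are dropped from normalization with a warning", {
  d <- tibble::tibble(
    session = rep(1:2, each = 3), contrast = rep(c(0, 50, 100), 2),
    max_value = c(1, 2, 3, 5, 5, 5)
  )
  expect_warning(out <- normalize_curve_max(d, max_value, session), "constant")
  expect_equal(unique(out$session), 1)
  expect_error(
    suppressWarnings(normalize_curve_max(
      tibble::tibble(session = 1, contrast = c(0, 1), max_value = c(2, 2)),
      max_value, session
    )),
    "no curves"
  )
})

test_that("correlation map is 1 for the regressor, sign-blind, 0 on flat voxels", {
  tl <- tl60
  reg <- stimulus_boxcar(tl)
  delta <- array(0, dim = c(2, 2, 60))
  delta[1, 1, ] <- reg
  delta[1, 2, ] <- -3 * reg
  delta[2, 1, ] <- 5 # constant
  delta[2, 2, ] <- reg + rnorm(60, sd = 1e-3)
  cm <- correlation_map(delta, tl)
  expect_equal(cm$r2[cm$row == 1 & cm$col == 1], 1, tolerance = 1e-12)
  expect_equal(cm$r2[cm$row == 1 & cm$col == 2], 1, tolerance = 1e-12)
  expect_equal(cm$r2[cm$row == 2 & cm$col == 1], 0)
  expect_true(all(cm$r2 >= 0 & cm$r2 <= 1))
})

test_that("white-noise voxels have null mean r2 near 1/(frames - 1)", {
  tl <- trial_timeline() # 170 frames
  withr::with_seed(4, {
    delta <- array(rnorm(60 * 40 * 170), dim = c(60, 40, 170))
  })
  cm <- correlation_map(delta, tl)
  expect_equal(mean(cm$r2), 1 / 169, tolerance = 0.1)
})

test_that("spike binning groups 5 contacts and uses half-open 0.2-s windows", {
  tl <- trial_timeline()
  st <- tibble::tibble(contact = 1, time_s = c(0.05, 0.15, 0.25))
  out <- bin_spikes(st, n_contacts = 20, timeline = tl)
  expect_equal(dim(out), c(4, 170, 1))
  expect_equal(out[1, 1:3, 1], c(2, 1, 0))
  # spike at an exact edge goes to the later bin
  out2 <- bin_spikes(
    tibble::tibble(contact = 6, time_s = 0.2),
    n_contacts = 20, timeline = tl
  )
  expect_equal(out2[2, 2, 1], 1)
  expect_equal(sum(out2), 1)
  # rate output divides by the bin width
  out3 <- bin_spikes(st,
    n_contacts = 20, timeline = tl, output = "rate"
  )
  expect_equal(out3[1, 1, 1], 10)
})

test_that("spike binning conserves counts and drops partial contact groups", {
  tl <- trial_timeline()
  withr::with_seed(11, {
    st <- tibble::tibble(
      contact = sample(1:20, 500, replace = TRUE),
      time_s = runif(500, 0, 34 - 1e-9),
      trial = sample(1:3, 500, replace = TRUE)
    )
  })
  out <- bin_spikes(st, n_contacts = 20, timeline = tl)
  expect_equal(sum(out), 500)
  expect_equal(dim(out)[3], 3)
  # 23 contacts: the 3 extra contacts are dropped, with a warning
  st23 <- dplyr::bind_rows(
    st, tibble::tibble(contact = 21:23, time_s = 1, trial = 1)
  )
  expect_warning(out23 <- bin_spikes(st23, n_contacts = 23, timeline = tl),
    regexp = "trailing"
  )
  expect_equal(sum(out23), 500)
  # no spikes at all: an all-zero block
  empty <- bin_spikes(
    tibble::tibble(contact = integer(0), time_s = numeric(0)),
    n_contacts = 10, timeline = tl
  )
  expect_equal(sum(empty), 0)
  expect_equal(dim(empty)[1], 2)
  # out-of-range times are rejected
  expect_error(
    bin_spikes(tibble::tibble(contact = 1, time_s = 34),
      n_contacts = 5, timeline = tl
    ),
    "within"
  )
})

test_that("responsive sessions are kept; unresponsive or off-target dropped", {
  s <- noisy_session()
  inc <- include_session(s)
  expect_true(inc$keep)
  expect_true(inc$crosses_region)
  expect_lt(inc$p_fus, 0.05)
  expect_lt(inc$p_spikes, 0.05)

  s0 <- gen_session(tiny_config(contrasts = 0, n_trials = 6), seed = 31)
  inc0 <- include_session(s0)
  expect_false(inc0$keep)
  expect_match(inc0$reason, "significant")

  off <- probe_trajectory(24, 45, 0, 20) # outside the region columns
  inc_off <- include_session(s, off)
  expect_false(inc_off$keep)
  expect_false(inc_off$crosses_region)
  expect_match(inc_off$reason, "cross")
})
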
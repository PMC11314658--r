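test_that("first-order detrending removes exactly the least-squares line", {
  fs <- 10
  t <- (0:999) / fs
  line <- 2 + 0.3 * t
  out <- detrend_poly1(line, fs)
  expect_lt(max(abs(out$series)), 1e-10 * max(abs(line)))
  expect_equal(unname(out$trend_coef["slope", 1]), 0.3, tolerance = 1e-10)

  # many-period zero-mean sinusoid is nearly untouched
  x <- sin(2 * pi * 0.5 * t)
  outs <- detrend_poly1(x, fs)
  expect_lt(max(abs(outs$series - x)), 0.02)

  # residuals have zero mean and zero refit slope (projection idempotence)
  set.seed(1)
  y <- cumsum(rnorm(500))
  outy <- detrend_poly1(y)
  expect_lt(abs(mean(outy$series)), 1e-10)
  refit <- detrend_poly1(outy$series)
  expect_lt(max(abs(refit$series - outy$series)), 1e-9)

  expect_error(detrend_poly1(1), class = "fnirseeg_invalid_parameter")
})

test_that("TDDR is near-identity on clean data and downweights spikes", {
  fs <- 10
  t <- (0:2999) / fs
  clean <- 0.5 * sin(2 * pi * 0.05 * t) + 0.1 * sin(2 * pi * 0.3 * t)

  out <- tddr(clean, fs)
  expect_gt(stats::cor(out$series, clean), 0.99)
  expect_true(all(out$weights >= 0 & out$weights <= 1))
  expect_lte(out$iterations, 50)

  # constant signal passes through with all weights 1
  const <- tddr(rep(2.5, 100), fs)
  expect_lt(diff(range(const$series)), 1e-12)
  expect_true(all(const$weights == 1))

  expect_error(tddr(c(1, 2), fs), class = "fnirseeg_invalid_parameter")
})

test_that("TDDR strictly reduces RMSE against ground truth for 10-sigma spikes", {
  fs <- 10
  t <- (0:2999) / fs
  for (seed in 1:5) {
    set.seed(seed)
    clean <- 0.5 * sin(2 * pi * 0.05 * t) + rnorm(length(t), 0, 0.05)
    spike_amp <- 10 * stats::sd(clean)
    art <- inject_motion_artifacts(clean, spike_times = c(80, 200),
                                   spike_amps = c(spike_amp, -spike_amp),
                                   shift_times = 150,
                                   shift_amps = 5 * stats::sd(clean),
                                   fs = fs)
    out <- tddr(art$series, fs)
    rmse_pre <- sqrt(mean((art$series - clean)^2))
    rmse_post <- sqrt(mean((out$series - clean)^2))
    expect_lt(rmse_post, rmse_pre)
    # weights collapse to ~0 inside the spikes
    spike_idx <- round(80 * fs) + (-2:2)
    expect_lt(min(out$weights[spike_idx]), 0.1)
  }
})

test_that("the cleaning report records trend, TDDR and filter parameters", {
  sch <- make_stroop_schedule(seed = 1)
  sim <- simulate_hemodynamics(sch, fs = 10, seed = 2)
  res <- clean_fnirs(sim$hemo)
  rep <- res$report
  expect_named(rep$trend_coef, c("hbo2", "hbr"))
  expect_gte(rep$tddr$iterations, 1)
  expect_true(rep$tddr$converged)
  expect_identical(rep$filter$order, 3)
  expect_equal(rep$filter$cutoff, c(0.01, 0.08))
  # realized single-pass -3 dB points bracket the nominal band
  expect_equal(unname(rep$filter$realized_3db["low"]), 0.01,
               tolerance = 0.05)
  expect_equal(unname(rep$filter$realized_3db["high"]), 0.08,
               tolerance = 0.05)
})

test_that("response peaks are the prominent local extrema in order", {
  fs <- 10
  t <- (0:1199) / fs
  boundaries <- c(waiting = 0, task = 20, rest = 80, end = 120)

  # single bump: one maximum at the apex (within one sample)
  bump <- exp(-(t - 50)^2 / (2 * 5^2))
  hemo <- new_hemo_series(t, fs, matrix(bump), matrix(-0.3 * bump), "ch1")
  pk <- extract_response_peaks(hemo, boundaries)
  expect_identical(nrow(pk$hbo2[pk$hbo2$type == "max", ]), 1L)
  expect_equal(pk$hbo2$time[pk$hbo2$type == "max"], 50, tolerance = 0.1)

  # monotone series: no peaks
  mono <- new_hemo_series(t, fs, matrix(t / 100), matrix(-t / 300), "ch1")
  pk2 <- extract_response_peaks(mono, boundaries)
  expect_identical(nrow(pk2$hbo2), 0L)

  # two-bump HbR with known apexes: first and second minima found in order
  two <- -exp(-(t - 40)^2 / (2 * 4^2)) - 0.8 * exp(-(t - 75)^2 / (2 * 4^2))
  hemo3 <- new_hemo_series(t, fs, matrix(-two), matrix(two), "ch1")
  pk3 <- extract_response_peaks(hemo3, boundaries)
  expect_equal(nth_peak(pk3$hbr, 1, "min"), min(two), tolerance = 1e-6)
  mins <- pk3$hbr[pk3$hbr$type == "min", ]
  expect_identical(nrow(mins), 2L)
  expect_equal(mins$time, c(40, 75), tolerance = 0.1)
  expect_true(is.na(nth_peak(pk3$hbr, 3, "min")))

  expect_error(extract_response_peaks(hemo, c(0, 500, 600, 700)),
               class = "fnirseeg_invalid_parameter")
})

test_that("the full cleaning chain beats no cleaning on contaminated sessions", {
  wins <- 0
  for (s in 1:8) {
    sch <- make_stroop_schedule(seed = 70 + s)
    sim <- simulate_hemodynamics(sch, fs = 10, seed = 170 + s)
    sim <- inject_motion_artifacts(sim, spike_times = c(45, 70),
                                   spike_amps = c(1.5, -1),
                                   shift_times = 55, shift_amps = 1)
    raw <- forward_mbll(sim$hemo)
    rec <- invert_mbll(optical_density(raw, i0 = raw$i0))
    cl <- clean_fnirs(rec)$hemo
    r_raw <- stats::cor(rec$hbo2[, 1], sim$truth$hbo2[, 1])
    r_cl <- stats::cor(cl$hbo2[, 1], sim$truth$hbo2[, 1])
    if (r_cl > r_raw) wins <- wins + 1
  }
  expect_gte(wins, 7)
})
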
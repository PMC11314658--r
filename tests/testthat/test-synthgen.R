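no_noise <- physio_noise_cfg(mayer_amp = 0, resp_amp = 0, cardiac_amp = 0,
                             drift_slope = 0, white_sd = 0)

test_that("no noise and no trials give an identically zero series", {
  sch <- make_stroop_schedule(n_trials = 0, seed = 1)
  sim <- simulate_hemodynamics(sch, fs = 10, noise_cfg = no_noise, seed = 2)
  expect_true(all(sim$hemo$hbo2 == 0))
  expect_true(all(sim$hemo$hbr == 0))
  expect_true(all(sim$hemo$hbt == 0))
})

test_that("HbR changes are opposite-signed and smaller than HbO2", {
  sch <- make_stroop_schedule(seed = 3)
  sim <- simulate_hemodynamics(sch, fs = 10, amp_hbo2 = 0.5, seed = 4)
  expect_lt(max(abs(sim$hemo$hbr)), max(abs(sim$hemo$hbo2)))
  # noise-free activations are exact scalings of each other
  expect_equal(sim$truth$hbr, -0.25 * sim$truth$hbo2, tolerance = 1e-12)
})

test_that("a Mayer-only noise configuration puts its power at 0.1 Hz", {
  sch <- make_stroop_schedule(n_trials = 0, wait_s = 30, rest_s = 150,
                              seed = 5)
  cfg <- physio_noise_cfg(mayer_amp = 0.2, resp_amp = 0, cardiac_amp = 0,
                          drift_slope = 0, white_sd = 0)
  sim <- simulate_hemodynamics(sch, fs = 10, noise_cfg = cfg, seed = 6)
  x <- sim$hemo$hbo2[, 1]
  fs <- 10
  df <- fs / length(x)
  expect_equal(dominant_freq(x, fs), 0.1, tolerance = 2 * df / 0.1)
  # spectral peak height consistent with power a^2 / 2, i.e. amplitude a
  expect_equal(fitted_amp(x, fs, 0.1), 0.2, tolerance = 0.02)
})

test_that("hbt equals hbo2 + hbr to numerical precision throughout", {
  sch <- make_stroop_schedule(seed = 7)
  sim <- simulate_hemodynamics(sch, fs = 10, seed = 8)
  expect_lt(max(abs(sim$hemo$hbt - (sim$hemo$hbo2 + sim$hemo$hbr))), 1e-12)
})

test_that("identical seeds reproduce the simulation bit for bit", {
  sch <- make_stroop_schedule(seed = 9)
  a <- simulate_hemodynamics(sch, fs = 10, seed = 10)
  b <- simulate_hemodynamics(sch, fs = 10, seed = 10)
  expect_identical(a$hemo$hbo2, b$hemo$hbo2)
  expect_false(identical(a$hemo$hbo2,
                         simulate_hemodynamics(sch, fs = 10,
                                               seed = 11)$hemo$hbo2))
  expect_error(simulate_hemodynamics(sch, fs = -1, seed = 1),
               class = "fnirseeg_invalid_parameter")
})

test_that("motion artifact injection matches its definitions and log", {
  fs <- 10
  x <- sin(2 * pi * 0.05 * (0:999) / fs)
  # empty artifact lists: unchanged bit for bit
  out0 <- inject_motion_artifacts(x, fs = fs)
  expect_identical(out0$series, x)

  # one step of amplitude s at time t0: difference exactly s for t >= t0
  out1 <- inject_motion_artifacts(x, shift_times = 40, shift_amps = 2.5,
                                  fs = fs)
  t <- (0:999) / fs
  d <- out1$series - x
  expect_true(all(d[t >= 40] == 2.5))
  expect_true(all(d[t < 40] == 0))

  # two spikes: log has exactly two spike entries at the stated times
  out2 <- inject_motion_artifacts(x, spike_times = c(20, 60),
                                  spike_amps = c(3, -2), fs = fs)
  log2 <- out2$artifact_log
  expect_identical(log2$type, c("spike", "spike"))
  expect_identical(log2$time, c(20, 60))
  expect_identical(log2$amplitude, c(3, -2))

  expect_error(inject_motion_artifacts(x, spike_times = 500, spike_amps = 1,
                                       fs = fs),
               class = "fnirseeg_invalid_parameter")
})

test_that("the forearm occlusion model has the expected shape", {
  # zero slopes: flat zero series
  flat <- simulate_forearm_block(slopes = c(hbo2 = 0, hbr = 0), fs = 10)
  expect_true(all(flat$hemo$hbo2 == 0) && all(flat$hemo$hbr == 0))

  fb <- simulate_forearm_block(fs = 10, noise_sd = 0)
  t <- fb$hemo$time
  p <- fb$params$phase_times
  occ <- t > p[["t1"]] & t < p[["t2"]]
  # opposite signs throughout occlusion
  expect_true(all(sign(fb$hemo$hbo2[occ, 1]) == -sign(fb$hemo$hbr[occ, 1])))
  # HbO2 drops monotonically while the cuff is inflated
  expect_true(all(diff(fb$hemo$hbo2[occ, 1]) <= 0))
  # post-release overshoot beyond baseline
  post <- t > p[["t2"]]
  expect_gt(max(fb$hemo$hbo2[post, 1]), 0)
  expect_lt(min(fb$hemo$hbr[post, 1]), 0)

  # final 10 s mean agrees with the analytic biexponential decay
  e <- fb$params$slopes[["hbo2"]] * unname(fb$params$durations[[2]])
  o <- -fb$params$overshoot_frac * e
  Td <- p[["t3"]] - p[["t2"]]
  f1 <- fb$params$tau_fast; f2 <- fb$params$tau_slow
  closed <- ((e - o) * f1 * (exp(-(Td - 10) / f1) - exp(-Td / f1)) +
               o * f2 * (exp(-(Td - 10) / f2) - exp(-Td / f2))) / 10
  tail10 <- t >= p[["t3"]] - 10
  expect_equal(mean(fb$hemo$hbo2[tail10, 1]), closed, tolerance = 0.02)

  expect_error(simulate_forearm_block(durations = c(0, 60, 90)),
               class = "fnirseeg_invalid_parameter")
})
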
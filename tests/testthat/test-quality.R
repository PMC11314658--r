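test_that("input-referred noise recovers the injected chain noise", {
  fs <- 1000
  zeros <- new_eeg_recording(matrix(0, 60 * fs, 1), fs, "Fp1")

  out <- acquisition_chain(zeros, noise_rms = 0.8, seed = 3)
  expect_equal(input_referred_noise(out), 0.8, tolerance = 0.1)

  # zero-noise chain: numerically silent
  quiet <- acquisition_chain(zeros)
  expect_lt(input_referred_noise(quiet), 1e-9)

  # invariant to a pure DC offset (mean removal)
  shifted <- out
  shifted$samples <- shifted$samples + 42
  expect_equal(input_referred_noise(shifted), input_referred_noise(out),
               tolerance = 1e-12)

  short <- new_eeg_recording(matrix(0, fs, 1), fs, "Fp1")
  expect_error(input_referred_noise(short),
               class = "fnirseeg_invalid_parameter")
})

test_that("white noise through the 50 Hz front end follows the noise-bandwidth closed form", {
  fs <- 1000
  set.seed(9)
  sigma <- 5
  wn <- new_eeg_recording(matrix(rnorm(60 * fs, 0, sigma), 60 * fs, 1),
                          fs, "Fp1")
  measured <- input_referred_noise(acquisition_chain(wn))
  # order-2 Butterworth noise-equivalent bandwidth: fc * (pi/4) / sin(pi/4)
  neb <- 50 * (pi / 4) / sin(pi / 4)
  expect_equal(measured, sigma * sqrt(neb / (fs / 2)), tolerance = 0.05)
})

test_that("amplitude distortion measures gain error against the generator", {
  # ideal unity chain: zero distortion
  rec <- tone_recording(10, amp = 100, duration = 20)
  expect_lt(amplitude_distortion(rec, 10, 100), 1e-9)

  # default chain at 10 Hz / 100 uV stays under the 2 percent spec bound
  out <- acquisition_chain(rec)
  expect_lt(amplitude_distortion(out, 10, 100), 2)

  # constructed 5 percent gain error reads 5 +/- 0.1
  bad <- rec
  bad$samples <- 1.05 * bad$samples
  expect_equal(amplitude_distortion(bad, 10, 100), 5, tolerance = 0.1 / 5)

  # scale invariance for a linear chain
  half <- tone_recording(10, amp = 50, duration = 20)
  expect_equal(amplitude_distortion(acquisition_chain(half), 10, 50),
               amplitude_distortion(out, 10, 100), tolerance = 1e-6)

  expect_warning(amplitude_distortion(rec, 60, 100),
                 class = "fnirseeg_outside_passband")
})

test_that("frequency distortion resolves 0.1 percent offsets via peak interpolation", {
  rec <- tone_recording(10, amp = 100, duration = 100)
  expect_lt(frequency_distortion(rec, 10), 0.1)

  off <- tone_recording(10.05, amp = 100, duration = 100)
  expect_equal(frequency_distortion(off, 10), 0.5, tolerance = 0.05 / 0.5)

  zero <- tone_recording(10, amp = 0, duration = 100)
  expect_error(frequency_distortion(zero, 10),
               class = "fnirseeg_degenerate_input")
  short <- tone_recording(10, amp = 100, duration = 5)
  expect_error(frequency_distortion(short, 10),
               class = "fnirseeg_invalid_parameter")
})

test_that("crosstalk residual separates high from low switching frequencies", {
  base <- tone_recording(7, amp = 20, duration = 10)

  r125 <- crosstalk_residual(base, inject_crosstalk(base, 125, 10))
  expect_lt(r125$residual_ratio, 5)
  expect_gt(r125$rejection_db, 26)

  r30 <- crosstalk_residual(base, inject_crosstalk(base, 30, 10))
  expect_gt(r30$residual_ratio, 50)

  # monotone non-increasing residual across the switching-frequency ladder
  ratios <- vapply(c(30, 60, 125, 250), function(fsw) {
    crosstalk_residual(base, inject_crosstalk(base, fsw, 10))$residual_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) <= 1e-9))

  expect_error(crosstalk_residual(base, base),
               class = "fnirseeg_degenerate_input")
  other <- tone_recording(7, amp = 20, duration = 5)
  expect_error(crosstalk_residual(base, other),
               class = "fnirseeg_invalid_parameter")
})

test_that("the assembled quality report is finite and non-negative", {
  q <- quality_report(duration_s = 120, seed = 2)
  vals <- c(q$input_referred_noise, q$amplitude_distortion,
            q$frequency_distortion, q$crosstalk_residual_ratio)
  expect_true(all(is.finite(vals)))
  expect_true(all(vals >= 0))
  expect_lt(q$amplitude_distortion, 2)
  expect_lt(q$frequency_distortion, 1)
})
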
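test_that("the acquisition chain passes the EEG band and rejects above it", {
  # DC is preserved after referral back to input units
  n <- 2000
  dc <- new_eeg_recording(matrix(1, n, 1), 1000, "Fp1")
  out <- acquisition_chain(dc)
  expect_equal(unname(out$samples[n, 1]), 1, tolerance = 1e-6)

  # 10 Hz passband tone preserved within 5 percent
  t10 <- tone_recording(10, amp = 50, duration = 10)
  a10 <- fitted_amp(acquisition_chain(t10)$samples[2000:10000, 1], 1000, 10)
  expect_equal(a10, 50, tolerance = 0.05)

  # 200 Hz attenuated below 10 percent
  t200 <- tone_recording(200, amp = 50, duration = 10)
  a200 <- fitted_amp(acquisition_chain(t200)$samples[2000:10000, 1], 1000, 200)
  expect_lt(a200, 5)

  expect_error(acquisition_chain(t10, lpf_cutoff = 600),
               class = "fnirseeg_invalid_parameter")
  expect_error(acquisition_chain(t10, noise_rms = 1),
               class = "fnirseeg_invalid_parameter")
})

test_that("epoching follows the window arithmetic and drop policy", {
  fs <- 1000
  n <- 40 * fs
  eeg <- new_eeg_recording(matrix(rnorm(n * 2), n, 2), fs, c("Fp1", "Fp2"))

  markers <- data.frame(onset = seq(2, 31, by = 1),
                        condition = rep("incongruent", 30))
  ep <- epoch_eeg(eeg, markers)
  expect_identical(dim(ep$epochs), c(1000L, 30L, 2L))
  expect_identical(ep$dropped, 0L)

  # a marker at t = 0 cannot fit the -250 ms pre-window: dropped and counted
  m2 <- data.frame(onset = c(0, 5), condition = c("a", "b"))
  ep2 <- epoch_eeg(eeg, m2)
  expect_identical(ep2$dropped, 1L)
  expect_identical(dim(ep2$epochs)[2], 1L)

  expect_error(epoch_eeg(eeg, data.frame(onset = 0, condition = "a")),
               class = "fnirseeg_empty_epochs")
})

test_that("baseline correction zeroes the pre-stimulus mean and only that", {
  fs <- 1000
  n <- 10 * fs
  eeg <- new_eeg_recording(matrix(3.5, n, 1), fs, "Fp1")
  ep <- epoch_eeg(eeg, data.frame(onset = c(2, 5), condition = c("a", "a")))
  bc <- baseline_correct(ep)
  expect_lt(max(abs(bc$epochs)), 1e-12)

  # ramp: baseline mean removed, post-stimulus shape preserved up to offset
  ramp <- new_eeg_recording(matrix((1:n) / fs, n, 1), fs, "Fp1")
  epr <- baseline_correct(epoch_eeg(ramp,
                                    data.frame(onset = 3, condition = "a")))
  sel <- epr$rel_time >= -0.25 & epr$rel_time < 0
  expect_lt(abs(mean(epr$epochs[sel, 1, 1])), 1e-12)
  post <- epr$epochs[epr$rel_time >= 0, 1, 1]
  expect_equal(diff(post), rep(1 / fs, length(post) - 1), tolerance = 1e-9)
})

test_that("averaging is exact for identical epochs and linear overall", {
  fs <- 1000
  n <- 20 * fs
  base <- sin(2 * pi * 10 * (seq_len(n) - 1) / fs)
  eeg <- new_eeg_recording(matrix(base, n, 1), fs, "Fp1")
  markers <- data.frame(onset = seq(1, 15, by = 1),  # integer s: same phase
                        condition = rep("a", 15))
  ep <- epoch_eeg(eeg, markers)
  avg <- average_erp(ep, band = NULL)
  expect_equal(avg$erp[, 1], ep$epochs[, 1, 1], tolerance = 1e-12)

  # a 10 Hz component inside 0.8-17 Hz survives filtering within 10 percent
  avgf <- average_erp(ep)
  mid <- avg$rel_time > -0.2 & avg$rel_time < 0.7
  expect_equal(sqrt(mean(avgf$erp[mid, 1]^2)),
               sqrt(mean(avg$erp[mid, 1]^2)), tolerance = 0.1)

  # linearity of epoch -> baseline -> average on a random pair
  set.seed(3)
  e1 <- new_eeg_recording(matrix(rnorm(n), n, 1), fs, "Fp1")
  e2 <- new_eeg_recording(matrix(rnorm(n), n, 1), fs, "Fp1")
  comb <- new_eeg_recording(2 * e1$samples - 3 * e2$samples, fs, "Fp1")
  f <- function(e) {
    average_erp(baseline_correct(epoch_eeg(e, markers)))$erp
  }
  expect_equal(f(comb), 2 * f(e1) - 3 * f(e2), tolerance = 1e-9)
})

test_that("component amplitudes are window means with fixed windows", {
  rel <- seq(-250, 749) / 1000
  mk_erp <- function(v) {
    structure(list(erp = matrix(v, ncol = 1), rel_time = rel, fs = 1000,
                   channels = "Fp1", windows = erp_component_windows()),
              class = "erp_result")
  }
  z <- mk_erp(rep(0, 1000))
  expect_identical(unname(component_amplitude(z, "P450")), 0)

  one <- mk_erp(rep(1, 1000))
  for (cn in c("P450", "N500", "P600")) {
    expect_equal(unname(component_amplitude(one, cn)), 1)
  }

  # -5 uV only inside [450, 550) ms: N500 = -5, P450 = 0, P600 = 0
  v <- ifelse(rel >= 0.45 & rel < 0.55, -5, 0)
  e <- mk_erp(v)
  expect_equal(unname(component_amplitude(e, "N500")), -5)
  expect_identical(unname(component_amplitude(e, "P450")), 0)
  expect_identical(unname(component_amplitude(e, "P600")), 0)

  expect_error(component_amplitude(z, "P300"),
               class = "fnirseeg_invalid_parameter")
})

test_that("recovered component amplitudes converge to the template values", {
  tpl <- make_erp_template()
  comps <- vapply(1:6, function(s) {
    sch <- make_stroop_schedule(n_trials = 160, seed = 100 + s)
    eeg <- simulate_eeg(sch, erp_templates = tpl,
                        background_cfg = quiet_bg(rms = 10), seed = 200 + s)
    rowMeans(average_erp(baseline_correct(epoch_eeg(eeg)))$components)
  }, numeric(3))
  err <- abs(rowMeans(comps) - c(-2.7, -4.0, -2.0))
  expect_lt(max(err), 0.3)
})

test_that("high-frequency LED switching leaves ERP components untouched, low does not", {
  tpl <- make_erp_template()
  sch <- make_stroop_schedule(seed = 11)
  eeg <- simulate_eeg(sch, erp_templates = tpl, seed = 12)
  comps <- function(e) {
    average_erp(baseline_correct(epoch_eeg(acquisition_chain(e))))$components
  }
  c0 <- comps(eeg)
  pert125 <- max(abs(comps(inject_crosstalk(eeg, 125, 10)) - c0))
  pert30 <- max(abs(comps(inject_crosstalk(eeg, 30, 10)) - c0))
  expect_lt(pert125, 0.1)
  expect_gt(pert30, 0.1)
  expect_gt(pert30, pert125)
})
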
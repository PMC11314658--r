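#' Input-referred noise of an acquisition chain
#'
#' RMS of the mean-removed, input-referred output of the EEG chain with a
#' (nominally) zero input, i.e. the bench measurement of front-end noise.
#'
#' @param eeg an `eeg_recording` produced by [acquisition_chain()] with a
#'   zero input; record length must be at least `min_duration_s`.
#' @param min_duration_s minimum record length in seconds.
#' @return noise RMS in microvolts, one value per channel (a scalar for a
#'   single-channel recording).
#' @export
input_referred_noise <- function(eeg, min_duration_s = 10) {
  dur <- (nrow(eeg$samples) - 1) / eeg$fs
  if (dur < min_duration_s) {
    abort_fnirseeg(sprintf("record must be at least %g s long",
                           min_duration_s), "invalid_parameter")
  }
  out <- apply(eeg$samples, 2, function(x) rms(x - mean(x)))
  if (length(out) == 1) unname(out) else out
}

#' Amplitude distortion of a sinusoidal test signal
#'
#' Fits a sinusoid of known frequency to the chain output by least squares
#' (the bench practice of comparing against a signal generator) and reports
#' `100 * |A_measured - A_true| / A_true` percent.
#'
#' @param eeg the chain-output `eeg_recording` (single test channel used).
#' @param test_freq test frequency, Hz.
#' @param test_amp true generator amplitude, microvolts.
#' @param channel channel to evaluate.
#' @param passband_hz nominal chain passband edge; a test frequency at or
#'   above it triggers an outside-passband warning.
#' @return amplitude distortion in percent.
#' @export
amplitude_distortion <- function(eeg, test_freq, test_amp, channel = 1,
                                 passband_hz = 50) {
  check_positive(test_freq, "test_freq")
  check_positive(test_amp, "test_amp")
  if (test_freq >= passband_hz) {
    warn_fnirseeg("test frequency is outside the chain passband",
                  "outside_passband")
  }
  x <- eeg$samples[, channel]
  t <- (seq_along(x) - 1) / eeg$fs
  X <- cbind(sin(2 * pi * test_freq * t), cos(2 * pi * test_freq * t), 1)
  cf <- qr.solve(X, x)
  a_meas <- sqrt(cf[1]^2 + cf[2]^2)
  100 * abs(a_meas - test_amp) / test_amp
}

#' Frequency distortion of a sinusoidal test signal
#'
#' Measures the dominant output frequency by quadratic interpolation of the
#' Hann-windowed log-periodogram peak and reports
#' `100 * |f_measured - f_nominal| / f_nominal` percent. Requires a record
#' long enough that the spectral resolution is at most 0.1 percent of the
#' nominal frequency.
#'
#' @param eeg the chain-output `eeg_recording`.
#' @param nominal_freq nominal generator frequency, Hz.
#' @param channel channel to evaluate.
#' @return frequency distortion in percent.
#' @export
frequency_distortion <- function(eeg, nominal_freq, channel = 1) {
  check_positive(nominal_freq, "nominal_freq")
  x <- eeg$samples[, channel]
  n <- length(x)
  df <- eeg$fs / n
  if (df > 1e-3 * nominal_freq) {
    abort_fnirseeg("record too short for the required spectral resolution",
                   "invalid_parameter")
  }
  if (all(x == 0) || stats::sd(x) == 0) {
    abort_fnirseeg("signal has no spectral content", "degenerate_input")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  X <- Mod(stats::fft((x - mean(x)) * w))[seq_len(floor(n / 2))]
  k <- which.max(X)
  if (k <= 1 || k >= length(X)) {
    abort_fnirseeg("spectral peak at the edge of the analysis band",
                   "degenerate_input")
  }
  la <- log(X[k - 1]); lb <- log(X[k]); lc <- log(X[k + 1])
  delta <- 0.5 * (la - lc) / (la - 2 * lb + lc)
  f_meas <- (k - 1 + delta) * df
  100 * abs(f_meas - nominal_freq) / nominal_freq
}

#' Crosstalk residual after the acquisition chain
#'
#' Quantifies how much injected LED-switching crosstalk survives inside the
#' EEG band after the 50 Hz anti-alias front end. Both inputs are pre-chain
#' recordings differing only by the injected crosstalk; the function runs
#' both through the chain and reports
#' `residual_ratio = 100 * RMS(in-band difference after the chain) /
#' RMS(injected crosstalk before the chain)` and the corresponding
#' rejection in dB.
#'
#' @param eeg_clean pre-chain recording without crosstalk.
#' @param eeg_xtalk the same recording with crosstalk injected
#'   ([inject_crosstalk()]).
#' @param band analysis band in Hz (the EEG band of interest, 0-50 Hz).
#' @param settle_s seconds discarded at the start of both records before
#'   measuring, letting the front-end filter reach steady state (bench
#'   practice; the physical chain runs continuously).
#' @param ... passed to [acquisition_chain()] (e.g. `lpf_cutoff`).
#' @return list with `residual_ratio` (percent) and `rejection_db`.
#' @export
crosstalk_residual <- function(eeg_clean, eeg_xtalk, band = c(0, 50),
                               settle_s = 1, ...) {
  if (nrow(eeg_clean$samples) != nrow(eeg_xtalk$samples) ||
      eeg_clean$fs != eeg_xtalk$fs) {
    abort_fnirseeg("recordings must have identical length and sampling rate",
                   "invalid_parameter")
  }
  n <- nrow(eeg_clean$samples)
  keep <- seq_len(n) > round(settle_s * eeg_clean$fs)
  if (!any(keep)) {
    abort_fnirseeg("record shorter than the settle window",
                   "invalid_parameter")
  }
  injected <- (eeg_xtalk$samples - eeg_clean$samples)[keep, , drop = FALSE]
  denom <- rms(injected)
  if (denom == 0) {
    abort_fnirseeg("no crosstalk difference between the recordings",
                   "degenerate_input")
  }
  out_c <- acquisition_chain(eeg_clean, ...)
  out_x <- acquisition_chain(eeg_xtalk, ...)
  diffm <- (out_x$samples - out_c$samples)[keep, , drop = FALSE]
  inb <- apply_cols(diffm, function(v) bandlimit_fft(v, eeg_clean$fs, band))
  ratio <- 100 * rms(inb) / denom
  list(residual_ratio = ratio, rejection_db = -20 * log10(ratio / 100))
}

# keep only spectral content inside [band[1], band[2]] Hz (ideal FFT mask)
bandlimit_fft <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided
  X[f < band[1] | f > band[2]] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Assemble an acquisition-quality report
#'
#' Runs the standard bench-style evaluation on the simulated chain: noise
#' floor with zero input, amplitude/frequency distortion on a passband test
#' tone, and crosstalk residual at the configured LED switching frequency.
#'
#' @param fs EEG sampling rate, Hz.
#' @param noise_rms injected input-referred chain noise, uV RMS.
#' @param test_freq,test_amp distortion test tone (Hz, uV).
#' @param f_switch,xtalk_amp crosstalk injection settings (Hz, uV).
#' @param duration_s record length for the bench runs, seconds.
#' @param seed integer seed.
#' @return object of class `quality_report` with fields
#'   `input_referred_noise`, `amplitude_distortion`, `frequency_distortion`,
#'   `crosstalk_residual_ratio`, `crosstalk_rejection_db`.
#' @export
quality_report <- function(fs = 1000, noise_rms = 0.8, test_freq = 10,
                           test_amp = 100, f_switch = 125, xtalk_amp = 10,
                           duration_s = 120, seed = 1) {
  n <- round(duration_s * fs) + 1
  t <- (seq_len(n) - 1) / fs
  zeros <- new_eeg_recording(matrix(0, n, 1), fs, "test")
  noise_out <- acquisition_chain(zeros, noise_rms = noise_rms, seed = seed)
  irn <- input_referred_noise(noise_out)

  tone <- new_eeg_recording(matrix(test_amp * sin(2 * pi * test_freq * t),
                                   n, 1), fs, "test")
  tone_out <- acquisition_chain(tone)
  ad <- amplitude_distortion(tone_out, test_freq, test_amp)
  fd <- frequency_distortion(tone_out, test_freq)

  xt <- inject_crosstalk(tone, f_switch, xtalk_amp)
  cr <- crosstalk_residual(tone, xt)

  structure(list(
    input_referred_noise = irn,
    amplitude_distortion = ad,
    frequency_distortion = fd,
    crosstalk_residual_ratio = cr$residual_ratio,
    crosstalk_rejection_db = cr$rejection_db,
    settings = list(fs = fs, noise_rms = noise_rms, test_freq = test_freq,
                    test_amp = test_amp, f_switch = f_switch,
                    xtalk_amp = xtalk_amp, duration_s = duration_s,
                    seed = seed)
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  input-referred noise   %8.4f uV RMS\n",
              x$input_referred_noise))
  cat(sprintf("  amplitude distortion   %8.4f %%\n", x$amplitude_distortion))
  cat(sprintf("  frequency distortion   %8.4f %%\n", x$frequency_distortion))
  cat(sprintf("  crosstalk residual     %8.4f %% (rejection %.1f dB)\n",
              x$crosstalk_residual_ratio, x$crosstalk_rejection_db))
  invisible(x)
}
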
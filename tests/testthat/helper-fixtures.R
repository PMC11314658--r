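# shared fixtures, all generated in code at test time

quiet_bg <- function(rms = 0) {
  eeg_background_cfg(pink_rms = 0, white_rms = rms, alpha_amp = 0,
                     mains_amp = 0)
}

# short-session config keeping end-to-end tests fast
light_config <- function(...) {
  session_config(n_trials = 10, wait_s = 15, rest_s = 30,
                 background_cfg = eeg_background_cfg(pink_rms = 4,
                                                     white_rms = 4),
                 ...)
}

# deterministic single-channel sinusoid recording
tone_recording <- function(freq, amp = 1, fs = 1000, duration = 10,
                           channel = "Fp1") {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  new_eeg_recording(matrix(amp * sin(2 * pi * freq * t), n, 1), fs, channel)
}

# dominant frequency of a series from its periodogram
dominant_freq <- function(x, fs) {
  n <- length(x)
  X <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  (which.max(X) - 1) * fs / n
}

# least-squares sinusoid amplitude at a known frequency
fitted_amp <- function(x, fs, freq) {
  t <- (seq_along(x) - 1) / fs
  cf <- qr.solve(cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t), 1), x)
  sqrt(cf[1]^2 + cf[2]^2)
}
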
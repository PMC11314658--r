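#' Model the EEG acquisition chain
#'
#' Applies the front-end model of a patch EEG channel: an active low-pass
#' anti-alias filter (second-order Butterworth, 50 Hz), a x1000
#' instrumentation-amplifier gain, and additive input-referred noise. The
#' output is referred back to input units (divided by the gain) so that
#' downstream analysis stays in microvolts.
#'
#' @param eeg an `eeg_recording` (microvolts).
#' @param gain amplifier voltage gain (> 0); cancels in the referred output
#'   but is retained for reporting.
#' @param lpf_cutoff low-pass cutoff, Hz; must be below Nyquist.
#' @param lpf_order low-pass Butterworth order (active single-op-amp stage:
#'   2).
#' @param noise_rms input-referred noise RMS, microvolts.
#' @param seed seed for the noise draw (required when `noise_rms > 0`).
#' @return an `eeg_recording` in input-referred microvolts.
#' @export
acquisition_chain <- function(eeg, gain = 1000, lpf_cutoff = 50,
                              lpf_order = 2, noise_rms = 0, seed = NULL) {
  check_positive(gain, "gain")
  if (lpf_cutoff >= eeg$fs / 2) {
    abort_fnirseeg("LPF cutoff must be below Nyquist", "invalid_parameter")
  }
  lp <- butter_sos(lpf_order, lpf_cutoff, eeg$fs, "low")
  y <- sos_filter(lp, eeg$samples)  # causal: models the physical filter
  if (noise_rms > 0) {
    if (is.null(seed)) {
      abort_fnirseeg("`seed` is required when noise_rms > 0",
                     "invalid_parameter")
    }
    y <- y + with_seed(seed, matrix(stats::rnorm(length(y), 0, noise_rms),
                                    nrow(y), ncol(y)))
  }
  out <- eeg
  out$samples <- y
  attr(out, "chain") <- list(gain = gain, lpf_cutoff = lpf_cutoff,
                             lpf_order = lpf_order, noise_rms = noise_rms)
  out
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per event marker over a window relative to stimulus
#' onset (default -250 ms to +750 ms). Trials whose window would exceed the
#' record bounds are dropped and counted, never padded.
#'
#' @param eeg an `eeg_recording` with event markers (or supply `markers`).
#' @param markers optional data frame with `onset` (s) and `condition`.
#' @param window epoch window `c(start, end)` in seconds relative to onset.
#' @param baseline baseline window used later by [baseline_correct()].
#' @return object of class `epoch_set`: `epochs` array
#'   (time x trial x channel), `rel_time`, `conditions`, `dropped`,
#'   `window`, `baseline`.
#' @export
epoch_eeg <- function(eeg, markers = eeg$events, window = c(-0.25, 0.75),
                      baseline = c(-0.25, 0)) {
  fs <- eeg$fs
  n <- nrow(eeg$samples)
  rel_idx <- seq(round(window[1] * fs), round(window[2] * fs) - 1)
  keep <- logical(nrow(markers))
  for (i in seq_len(nrow(markers))) {
    i0 <- round(markers$onset[i] * fs) + 1L
    keep[i] <- (i0 + rel_idx[1]) >= 1 && (i0 + rel_idx[length(rel_idx)]) <= n
  }
  dropped <- sum(!keep)
  if (!any(keep)) {
    abort_fnirseeg("no marker has a complete epoch inside the record",
                   "empty_epochs")
  }
  kept <- which(keep)
  ep <- array(NA_real_,
              c(length(rel_idx), length(kept), length(eeg$channels)),
              dimnames = list(NULL, NULL, eeg$channels))
  for (k in seq_along(kept)) {
    i0 <- round(markers$onset[kept[k]] * fs) + 1L
    ep[, k, ] <- eeg$samples[i0 + rel_idx, , drop = FALSE]
  }
  structure(list(epochs = ep, rel_time = rel_idx / fs, fs = fs,
                 conditions = markers$condition[kept], dropped = dropped,
                 window = window, baseline = baseline,
                 channels = eeg$channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels, %d samples/epoch (%d dropped)\n",
              dim(x$epochs)[2], dim(x$epochs)[3], dim(x$epochs)[1],
              x$dropped))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts the per-trial, per-channel mean over the pre-stimulus baseline
#' window (default -250 ms to 0 ms) from each epoch.
#'
#' @param epochs an `epoch_set`.
#' @param baseline baseline window in seconds; defaults to the window stored
#'   with the epochs.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = epochs$baseline) {
  sel <- epochs$rel_time >= baseline[1] & epochs$rel_time < baseline[2]
  if (!any(sel)) {
    abort_fnirseeg("baseline window contains no samples", "invalid_parameter")
  }
  mu <- apply(epochs$epochs[sel, , , drop = FALSE], c(2, 3), mean)
  epochs$epochs <- sweep(epochs$epochs, c(2, 3), mu, "-")
  epochs
}

#' Zero-phase ERP band-pass on a short epoch
#'
#' Applies the ERP analysis band as a cascade of a zero-phase Butterworth
#' low-pass followed by a zero-phase high-pass; for a wide band such as
#' 0.8-17 Hz this realization is equivalent to a band-pass in the
#' passband. Because an IIR stage that removes strong above-band ripple
#' (e.g. residual LED-switching crosstalk) from a one-second epoch rings
#' well into the component windows, the cascade is preceded by a
#' linear-phase windowed-sinc FIR guard whose memory is finite: its edge
#' influence is confined to half the kernel length (50 ms by default),
#' strictly outside the P450/N500/P600 windows.
#'
#' @param x waveform vector or matrix (time x channel).
#' @param fs sampling rate, Hz.
#' @param band `c(low, high)` in Hz.
#' @param order Butterworth order of each cascade element.
#' @param guard_taps odd length of the FIR guard kernel (0 disables it);
#'   its cutoff sits midway between the band top and the guard's stopband.
#' @return the filtered waveform.
#' @export
erp_band_filter <- function(x, fs, band = c(0.8, 17), order = 4,
                            guard_taps = 101) {
  y <- x
  if (guard_taps > 0) {
    h <- fir_lowpass_taps(guard_taps, fc = 2.3 * band[2], fs = fs)
    y <- apply_cols(y, function(v) fir_zero_phase(h, v))
  }
  lp <- butter_sos(order, band[2], fs, "low")
  hp <- butter_sos(order, band[1], fs, "high")
  sos_filtfilt(hp, sos_filtfilt(lp, y))
}

# Hamming-windowed sinc low-pass kernel, unit DC gain, odd length
fir_lowpass_taps <- function(n, fc, fs) {
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  k <- -m:m
  h <- 2 * fc / fs * sinc_fn(2 * fc / fs * k)
  h <- h * (0.54 + 0.46 * cos(pi * k / m))
  h / sum(h)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Symmetric (zero-phase) FIR convolution with even (mirror) edge padding.
# Mirror padding is used deliberately: odd reflection doubles the edge
# sample into the padding's local mean, which converts zero-mean
# high-frequency ripple at the edge into a spurious low-frequency offset.
fir_zero_phase <- function(h, v) {
  m <- (length(h) - 1) / 2
  n <- length(v)
  ext <- c(v[seq(m + 1, 2)], v, v[seq(n - 1, n - m)])
  stats::convolve(ext, h, type = "filter")
}

#' Trial-average epochs into an ERP and band-pass the average
#'
#' Averages epochs across trials per channel, then applies the zero-phase
#' ERP analysis band-pass ([erp_band_filter()], default order 4,
#' 0.8-17 Hz) to the average -- average first, filter second. Component
#' amplitudes over the fixed P450/N500/P600 windows are attached.
#'
#' @param epochs an `epoch_set` (baseline-corrected).
#' @param band ERP band in Hz; `NULL` skips filtering.
#' @param order Butterworth order of the band-pass.
#' @param conditions optional subset of condition labels to average.
#' @return object of class `erp_result`: `erp` matrix (time x channel),
#'   `rel_time`, `components` (component x channel matrix of window means),
#'   `windows`, `n_trials`.
#' @export
average_erp <- function(epochs, band = c(0.8, 17), order = 4,
                        conditions = NULL) {
  keep <- if (is.null(conditions)) seq_len(dim(epochs$epochs)[2])
          else which(epochs$conditions %in% conditions)
  if (!length(keep)) abort_fnirseeg("no epochs to average", "empty_epochs")
  avg <- apply(epochs$epochs[, keep, , drop = FALSE], c(1, 3), mean)
  if (!is.null(band)) {
    avg <- erp_band_filter(avg, epochs$fs, band, order)
  }
  erp <- structure(list(erp = avg, rel_time = epochs$rel_time,
                        fs = epochs$fs, channels = epochs$channels,
                        windows = erp_component_windows(), band = band,
                        n_trials = length(keep)),
                   class = "erp_result")
  comp <- vapply(names(erp$windows),
                 function(cn) component_amplitude(erp, cn),
                 numeric(length(epochs$channels)))
  erp$components <- t(matrix(comp, ncol = length(erp$windows),
                             dimnames = list(epochs$channels,
                                             names(erp$windows))))
  erp
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf("<erp_result> %d trials averaged, channels: %s\n",
              x$n_trials, paste(x$channels, collapse = ", ")))
  print(round(x$components, 3))
  invisible(x)
}

#' ERP component amplitude
#'
#' Signed mean amplitude of the averaged waveform over a component's fixed
#' latency window (the windowed mean, not the extremum, so reported values
#' remain interpretable as mean +/- SD across sessions and polarity is not
#' forced).
#'
#' @param erp an `erp_result`.
#' @param component `"P450"`, `"N500"` or `"P600"`.
#' @return named numeric vector of amplitudes (uV), one per channel.
#' @export
component_amplitude <- function(erp, component) {
  w <- erp$windows[[component]]
  if (is.null(w)) {
    abort_fnirseeg(sprintf("unknown component '%s'", component),
                   "invalid_parameter")
  }
  if (w[1] < min(erp$rel_time) || w[2] > max(erp$rel_time) + 1 / erp$fs) {
    abort_fnirseeg("ERP does not cover the component window",
                   "invalid_parameter")
  }
  sel <- erp$rel_time >= w[1] & erp$rel_time < w[2]
  out <- colMeans(erp$erp[sel, , drop = FALSE])
  names(out) <- erp$channels
  out
}
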
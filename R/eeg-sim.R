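#' ERP component windows
#'
#' Fixed latency windows of the three prefrontal Stroop components measured
#' by the pipeline: P450 (400-450 ms), N500 (450-550 ms), P600 (600-700 ms)
#' after stimulus onset.
#'
#' @return named list of `c(start, end)` windows in seconds.
#' @export
erp_component_windows <- function() {
  list(P450 = c(0.400, 0.450),
       N500 = c(0.450, 0.550),
       P600 = c(0.600, 0.700))
}

#' Construct a filter-invariant ERP template
#'
#' Builds a smooth microvolt waveform on the epoch grid whose mean
#' amplitudes over the P450/N500/P600 windows equal the requested targets
#' both before and after the zero-phase ERP analysis band-pass. The
#' waveform is a minimum-norm combination of Gaussian bumps subject to
#' those window-mean constraints plus zero total area; because ERP
#' components are defined on band-passed averages, a template that is not
#' (near-)invariant under the analysis filter would have no recoverable
#' ground truth.
#'
#' @param targets named window means in microvolts for P450, N500, P600.
#' @param fs sampling rate, Hz.
#' @param window epoch window `c(start, end)` relative to onset, seconds.
#' @param band,band_order ERP analysis band (Hz) and Butterworth order the
#'   template is made invariant to.
#' @return object of class `erp_template`: `rel_time`, `waveform` (on the
#'   epoch grid; zero before onset), `onset_waveform` (the post-onset part
#'   added at each trial onset), `targets`, `windows`.
#' @examples
#' tpl <- make_erp_template()
#' sapply(erp_component_windows(), function(w) {
#'   mean(tpl$waveform[tpl$rel_time >= w[1] & tpl$rel_time < w[2]])
#' })
#' @export
make_erp_template <- function(targets = c(P450 = -2.7, N500 = -4.0,
                                          P600 = -2.0),
                              fs = 1000, window = c(-0.25, 0.75),
                              band = c(0.8, 17), band_order = 4) {
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1) / fs
  wins <- erp_component_windows()
  centers <- seq(0.06, 0.70, length.out = 9)
  sigma <- 0.04
  B <- vapply(centers, function(c0) {
    exp(-(rel - c0)^2 / (2 * sigma^2)) * (rel >= 0)
  }, numeric(length(rel)))

  FB <- apply(B, 2, function(col) erp_band_filter(col, fs, band, band_order))

  wmean <- function(x, w) mean(x[rel >= w[1] & rel < w[2]])
  A <- rbind(
    t(vapply(wins, function(w) apply(B, 2, wmean, w = w),
             numeric(ncol(B)))),
    t(vapply(wins, function(w) apply(FB, 2, wmean, w = w),
             numeric(ncol(B)))),
    colSums(B)
  )
  b <- c(targets[names(wins)], targets[names(wins)], 0)
  sv <- svd(A)
  coef <- sv$v %*% ((t(sv$u) %*% b) / sv$d)  # minimum-norm exact solution
  waveform <- drop(B %*% coef)

  structure(list(rel_time = rel, waveform = waveform,
                 onset_waveform = waveform[rel >= 0],
                 targets = targets, windows = wins, fs = fs,
                 band = band, band_order = band_order),
            class = "erp_template")
}

#' EEG background noise configuration
#'
#' @param pink_rms RMS of the 1/f-shaped background, microvolts.
#' @param white_rms RMS of the white background component, microvolts.
#' @param alpha_amp,alpha_freq amplitude (uV) and frequency (Hz) of an
#'   optional alpha-band sinusoid.
#' @param mains_amp,mains_freq optional mains interference (uV, Hz).
#' @return named list consumed by [simulate_eeg()].
#' @export
eeg_background_cfg <- function(pink_rms = 8, white_rms = 4,
                               alpha_amp = 2, alpha_freq = 10,
                               mains_amp = 0, mains_freq = 50) {
  list(pink_rms = pink_rms, white_rms = white_rms,
       alpha_amp = alpha_amp, alpha_freq = alpha_freq,
       mains_amp = mains_amp, mains_freq = mains_freq)
}

# 1/f-shaped Gaussian noise via spectral shaping, unit RMS
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))  # avoid dividing the DC bin
  f <- pmin(f, n - f + 1)    # symmetric shaping keeps the series real
  X <- X / sqrt(f)
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Construct an EEG recording
#'
#' @param samples microvolt matrix (time x channel).
#' @param fs sampling rate, Hz.
#' @param channels channel labels.
#' @param events data frame with columns `onset` (s) and `condition`.
#' @return object of class `eeg_recording`.
#' @export
new_eeg_recording <- function(samples, fs, channels = colnames(samples),
                              events = data.frame(onset = numeric(0),
                                                  condition = character(0))) {
  samples <- as.matrix(samples)
  check_positive(fs, "fs")
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  colnames(samples) <- channels
  dur <- (nrow(samples) - 1) / fs
  if (nrow(events) && (any(events$onset < 0) || any(events$onset > dur))) {
    abort_fnirseeg("event onsets must lie within the record",
                   "invalid_parameter")
  }
  structure(list(samples = samples, fs = fs, channels = channels,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %g Hz, channels: %s, %d events\n",
              nrow(x$samples), x$fs, paste(x$channels, collapse = ", "),
              nrow(x$events)))
  invisible(x)
}

#' Simulate a multi-channel EEG session with embedded ERP templates
#'
#' Generates background activity (1/f-shaped plus white noise, optional
#' alpha rhythm and mains interference) and adds each trial's
#' condition-specific ERP template aligned to its onset. Event markers are
#' stored with the recording.
#'
#' @param schedule an event schedule from [make_stroop_schedule()].
#' @param fs sampling rate, Hz (patch EEG rate: 1000).
#' @param erp_templates a single [make_erp_template()] used for both
#'   conditions, or a named list `list(congruent = , incongruent = )`.
#' @param background_cfg an [eeg_background_cfg()] list.
#' @param channels channel labels.
#' @param channel_scale per-channel multiplier on the evoked response
#'   (models lateralized component strength).
#' @param seed integer seed.
#' @return an `eeg_recording`.
#' @export
simulate_eeg <- function(schedule, fs = 1000,
                         erp_templates = make_erp_template(fs = fs),
                         background_cfg = eeg_background_cfg(),
                         channels = c("Fp1", "Fp2"),
                         channel_scale = rep(1, length(channels)), seed) {
  check_positive(fs, "fs")
  dur <- session_duration(schedule)
  n <- max(2L, round(dur * fs) + 1L)
  t <- (seq_len(n) - 1) / fs
  nch <- length(channels)
  if (inherits(erp_templates, "erp_template")) {
    erp_templates <- list(congruent = erp_templates,
                          incongruent = erp_templates)
  }

  tpl_len <- max(vapply(erp_templates,
                        function(x) length(x$onset_waveform), integer(1)))
  if (length(schedule$onsets) > 1) {
    min_gap <- min(diff(schedule$onsets))
    if (tpl_len / fs > min_gap) {
      warn_fnirseeg("ERP template is longer than the shortest trial spacing; responses overlap",
                    "overlap")
    }
  }

  cfg <- background_cfg
  samples <- with_seed(seed, {
    out <- matrix(0, n, nch)
    for (ch in seq_len(nch)) {
      bg <- numeric(n)
      if (cfg$pink_rms > 0) bg <- bg + cfg$pink_rms * pink_noise(n)
      if (cfg$white_rms > 0) bg <- bg + stats::rnorm(n, 0, cfg$white_rms)
      if (cfg$alpha_amp > 0) {
        bg <- bg + cfg$alpha_amp *
          sin(2 * pi * cfg$alpha_freq * t + stats::runif(1, 0, 2 * pi))
      }
      if (cfg$mains_amp > 0) {
        bg <- bg + cfg$mains_amp *
          sin(2 * pi * cfg$mains_freq * t + stats::runif(1, 0, 2 * pi))
      }
      out[, ch] <- bg
    }
    out
  })

  for (i in seq_along(schedule$onsets)) {
    wav <- erp_templates[[schedule$conditions[i]]]$onset_waveform
    i0 <- round(schedule$onsets[i] * fs) + 1L
    idx <- i0:min(n, i0 + length(wav) - 1L)
    for (ch in seq_len(nch)) {
      samples[idx, ch] <- samples[idx, ch] +
        channel_scale[ch] * wav[seq_along(idx)]
    }
  }

  new_eeg_recording(samples, fs, channels,
                    events = data.frame(onset = schedule$onsets,
                                        condition = schedule$conditions))
}

#' Inject LED-switching crosstalk into an EEG recording
#'
#' Models capacitive coupling of the fNIRS LED time-division-multiplexing
#' drive into the EEG channel as a zero-mean rectangular pulse train at the
#' switching frequency (AC-coupled: the empirical mean is removed so the
#' train is zero-mean to machine precision).
#'
#' @param eeg an `eeg_recording`.
#' @param f_switch LED switching frequency, Hz; must be below Nyquist.
#' @param amplitude peak coupling amplitude, microvolts.
#' @return the recording with crosstalk added to every channel.
#' @export
inject_crosstalk <- function(eeg, f_switch, amplitude) {
  if (f_switch <= 0) {
    abort_fnirseeg("`f_switch` must be > 0", "invalid_parameter")
  }
  if (f_switch >= eeg$fs / 2) {
    abort_fnirseeg("`f_switch` at or above Nyquist would alias", "aliasing")
  }
  if (amplitude == 0) return(eeg)
  n <- nrow(eeg$samples)
  # phase in sample units: k * f_switch and fs are exact in double
  # arithmetic, so duty transitions land deterministically on samples
  ph <- ((seq_len(n) - 1) * f_switch) %% eeg$fs
  x <- amplitude * ifelse(ph < eeg$fs / 2, 1, -1)
  x <- x - mean(x)
  eeg$samples <- eeg$samples + x
  attr(eeg, "crosstalk_params") <- list(f_switch = f_switch,
                                        amplitude = amplitude)
  eeg
}
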
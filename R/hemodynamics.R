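#' Canonical double-gamma haemodynamic response function
#'
#' The field-standard haemodynamic impulse response: a gamma density peaking
#' at `peak` seconds minus a `ratio`-scaled gamma density peaking at
#' `undershoot` seconds, normalized to unit peak amplitude.
#'
#' @param t time in seconds (vector, >= 0 contributes; negative times give 0).
#' @param peak time-to-peak of the positive lobe, seconds.
#' @param undershoot time-to-peak of the undershoot lobe, seconds.
#' @param ratio undershoot amplitude relative to the main lobe.
#' @return HRF values at `t`, unit peak.
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' h <- hrf_double_gamma(t)
#' t[which.max(h)]
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak + 1, scale = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, scale = 1)
  h[t < 0] <- 0
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

#' Physiological noise configuration for haemodynamic simulation
#'
#' Sinusoidal systemic components (Mayer waves ~0.1 Hz, respiration
#' 0.2-0.3 Hz, cardiac ~1 Hz) with per-channel random phases, plus linear
#' drift and white measurement noise. Amplitudes are in micromolar and apply
#' to the oxy-haemoglobin channel; the deoxy channel receives the same
#' components scaled by `hbr_scale`.
#'
#' @param mayer_hz,mayer_amp Mayer-wave frequency (Hz) and amplitude (uM).
#' @param resp_hz,resp_amp respiration frequency and amplitude.
#' @param cardiac_hz,cardiac_amp cardiac frequency and amplitude.
#' @param drift_slope linear drift slope, uM per second.
#' @param white_sd white-noise standard deviation, uM.
#' @param hbr_scale multiplier applied to all noise on the HbR series.
#' @return a named list consumed by [simulate_hemodynamics()].
#' @export
physio_noise_cfg <- function(mayer_hz = 0.1, mayer_amp = 0.1,
                             resp_hz = 0.25, resp_amp = 0.1,
                             cardiac_hz = 1.0, cardiac_amp = 0.05,
                             drift_slope = 0.005, white_sd = 0.02,
                             hbr_scale = 0.5) {
  list(mayer_hz = mayer_hz, mayer_amp = mayer_amp,
       resp_hz = resp_hz, resp_amp = resp_amp,
       cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
       drift_slope = drift_slope, white_sd = white_sd,
       hbr_scale = hbr_scale)
}

#' Simulate task-evoked haemodynamics with physiological noise
#'
#' Convolves the stimulus train of an event schedule with the canonical
#' double-gamma HRF, scales it per chromophore (HbR conventionally opposite
#' in sign and smaller than HbO2), and adds sinusoidal physiological
#' components at configured frequencies with random phases, a linear drift,
#' and white noise. The noise-free activation is retained as ground truth
#' for recovery scoring.
#'
#' @param schedule an [make_stroop_schedule()] event schedule.
#' @param fs sampling rate in Hz.
#' @param amp_hbo2 peak task-evoked HbO2 concentration change, micromolar.
#' @param amp_hbr peak HbR change; default `-0.25 * amp_hbo2`.
#' @param noise_cfg a [physio_noise_cfg()] list.
#' @param channels channel labels; activation is common to all channels,
#'   noise phases and white noise are drawn independently per channel.
#' @param seed integer seed.
#' @return an object of class `hemo_sim`: `hemo` (a `hemo_series` holding
#'   the noisy HbO2/HbR/HbT series), `truth` (noise-free activation matrices
#'   `hbo2`, `hbr`), `schedule`, `fs`, `noise_cfg`, `artifact_log` (empty),
#'   `seed`.
#' @export
simulate_hemodynamics <- function(schedule, fs = 100, amp_hbo2 = 0.5,
                                  amp_hbr = -0.25 * amp_hbo2,
                                  noise_cfg = physio_noise_cfg(),
                                  channels = c("Fp1", "Fp2"), seed) {
  check_positive(fs, "fs")
  dur <- session_duration(schedule)
  n <- max(2L, round(dur * fs) + 1L)
  t <- (seq_len(n) - 1) / fs
  nch <- length(channels)

  # unit-peak activation: impulse train convolved with the canonical HRF
  act <- numeric(n)
  if (length(schedule$onsets) > 0) {
    stim <- numeric(n)
    idx <- pmin(n, round(schedule$onsets * fs) + 1L)
    stim[idx] <- stim[idx] + 1
    hlen <- min(n, round(32 * fs))
    h <- hrf_double_gamma((seq_len(hlen) - 1) / fs)
    act <- stats::convolve(stim, rev(h), type = "open")[seq_len(n)]
    m <- max(abs(act))
    if (m > 0) act <- act / m
  }

  truth_hbo2 <- matrix(rep(act * amp_hbo2, nch), n, nch,
                       dimnames = list(NULL, channels))
  truth_hbr <- matrix(rep(act * amp_hbr, nch), n, nch,
                      dimnames = list(NULL, channels))

  noise <- with_seed(seed, {
    lapply(seq_len(nch), function(ch) {
      ph <- stats::runif(3, 0, 2 * pi)
      base <- noise_cfg$mayer_amp * sin(2 * pi * noise_cfg$mayer_hz * t + ph[1]) +
        noise_cfg$resp_amp * sin(2 * pi * noise_cfg$resp_hz * t + ph[2]) +
        noise_cfg$cardiac_amp * sin(2 * pi * noise_cfg$cardiac_hz * t + ph[3]) +
        noise_cfg$drift_slope * (t - mean(t)) * sample(c(-1, 1), 1)
      list(
        hbo2 = base + stats::rnorm(n, 0, noise_cfg$white_sd),
        hbr = noise_cfg$hbr_scale *
          (base + stats::rnorm(n, 0, noise_cfg$white_sd))
      )
    })
  })
  hbo2 <- truth_hbo2 + vapply(noise, `[[`, numeric(n), "hbo2")
  hbr <- truth_hbr + vapply(noise, `[[`, numeric(n), "hbr")

  structure(list(
    hemo = new_hemo_series(t, fs, hbo2, hbr, channels),
    truth = list(hbo2 = truth_hbo2, hbr = truth_hbr),
    schedule = schedule, fs = fs, noise_cfg = noise_cfg,
    artifact_log = data.frame(type = character(0), time = numeric(0),
                              amplitude = numeric(0)),
    seed = seed
  ), class = "hemo_sim")
}

#' Inject spike and baseline-shift motion artifacts
#'
#' Adds short Gaussian-shaped transients (spikes) and persistent step
#' changes (baseline shifts) to a haemodynamic series, returning the
#' contaminated series together with a log of every injected artifact so
#' that correction algorithms can be scored against ground truth. The same
#' artifact waveform is added to every channel and to both chromophores
#' (motion is common-mode across the optode array).
#'
#' @param x a `hemo_sim`, `hemo_series`, numeric matrix or vector.
#' @param spike_times,spike_amps spike centre times (s) and amplitudes (uM).
#' @param shift_times,shift_amps step onset times (s) and amplitudes (uM);
#'   each step persists to the end of the session.
#' @param spike_width_s standard deviation of the Gaussian spike, seconds.
#' @param fs sampling rate; taken from `x` when it carries one.
#' @return object of the same class as `x` with an `artifact_log` data frame
#'   attached (for plain matrices/vectors, a list `series` + `artifact_log`).
#' @export
inject_motion_artifacts <- function(x, spike_times = numeric(0),
                                    spike_amps = numeric(0),
                                    shift_times = numeric(0),
                                    shift_amps = numeric(0),
                                    spike_width_s = 0.3, fs = NULL) {
  if (inherits(x, "hemo_sim")) {
    res <- inject_motion_artifacts(x$hemo, spike_times, spike_amps,
                                   shift_times, shift_amps, spike_width_s)
    x$hemo <- res
    x$artifact_log <- rbind(x$artifact_log, attr(res, "artifact_log"))
    return(x)
  }
  if (inherits(x, "hemo_series")) {
    t <- x$time
    w <- artifact_waveform(t, spike_times, spike_amps, shift_times,
                           shift_amps, spike_width_s)
    x$hbo2 <- x$hbo2 + w
    x$hbr <- x$hbr + w
    x$hbt <- x$hbo2 + x$hbr
    attr(x, "artifact_log") <- w_log(spike_times, spike_amps, shift_times,
                                     shift_amps)
    return(x)
  }
  if (is.null(fs)) {
    abort_fnirseeg("`fs` is required for plain numeric input",
                   "invalid_parameter")
  }
  v <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  t <- (seq_len(nrow(v)) - 1) / fs
  w <- artifact_waveform(t, spike_times, spike_amps, shift_times,
                         shift_amps, spike_width_s)
  out <- v + w
  if (!is.matrix(x)) out <- drop(out)
  list(series = out,
       artifact_log = w_log(spike_times, spike_amps, shift_times, shift_amps))
}

artifact_waveform <- function(t, spike_times, spike_amps, shift_times,
                              shift_amps, spike_width_s) {
  dur <- t[length(t)]
  times <- c(spike_times, shift_times)
  if (length(times) && (any(times < 0) || any(times > dur))) {
    abort_fnirseeg("artifact times must lie within the session duration",
                   "invalid_parameter")
  }
  if (length(spike_times)) {
    spike_amps <- rep_len(spike_amps, length(spike_times))
    check_positive(spike_width_s, "spike_width_s")
  }
  if (length(shift_times)) shift_amps <- rep_len(shift_amps, length(shift_times))
  w <- numeric(length(t))
  for (i in seq_along(spike_times)) {
    w <- w + spike_amps[i] *
      exp(-(t - spike_times[i])^2 / (2 * spike_width_s^2))
  }
  for (i in seq_along(shift_times)) {
    w <- w + shift_amps[i] * (t >= shift_times[i])
  }
  w
}

w_log <- function(spike_times, spike_amps, shift_times, shift_amps) {
  data.frame(
    type = c(rep("spike", length(spike_times)),
             rep("shift", length(shift_times))),
    time = c(spike_times, shift_times),
    amplitude = c(rep_len(spike_amps, length(spike_times)),
                  rep_len(shift_amps, length(shift_times)))
  )
}

#' Simulate a forearm arterial-occlusion haemodynamic trace
#'
#' Piecewise model of the classic cuff-occlusion validation experiment:
#' a flat baseline; a slow linear HbO2 decrease and HbR increase while the
#' cuff blocks arterial flow; on release, a rapid biexponential rebound that
#' overshoots the baseline and then decays exponentially back to it.
#' For `t` seconds after release each chromophore follows
#' `(E - O) * exp(-t / tau_fast) + O * exp(-t / tau_slow)`, where `E` is the
#' end-of-occlusion value and `O = -overshoot_frac * E` the overshoot.
#'
#' @param durations named/ordered vector `c(baseline, occlusion, recovery)`
#'   in seconds; all > 0.
#' @param slopes vector `c(hbo2, hbr)` in uM/s during occlusion
#'   (conventionally negative for HbO2, positive for HbR).
#' @param overshoot_frac overshoot amplitude as a fraction of the
#'   end-of-occlusion deflection (opposite sign).
#' @param tau_fast,tau_slow rebound and return time constants, seconds.
#' @param fs sampling rate, Hz.
#' @param noise_sd white measurement noise, uM (0 for a deterministic trace).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return a `hemo_sim` object with single channel `"forearm"`; `truth`
#'   holds the noise-free trace and `params` the model constants.
#' @export
simulate_forearm_block <- function(durations = c(baseline = 30, occlusion = 60,
                                                 recovery = 90),
                                   slopes = c(hbo2 = -0.1, hbr = 0.05),
                                   overshoot_frac = 0.5, tau_fast = 2,
                                   tau_slow = 15, fs = 100, noise_sd = 0,
                                   seed = 0) {
  if (any(durations <= 0)) {
    abort_fnirseeg("all durations must be > 0", "invalid_parameter")
  }
  check_positive(fs, "fs")
  t1 <- durations[[1]]
  t2 <- t1 + durations[[2]]
  t3 <- t2 + durations[[3]]
  n <- round(t3 * fs) + 1L
  t <- (seq_len(n) - 1) / fs

  piecewise <- function(slope) {
    e <- slope * durations[[2]]
    o <- -overshoot_frac * e
    y <- numeric(n)
    occ <- t >= t1 & t < t2
    y[occ] <- slope * (t[occ] - t1)
    rel <- t >= t2
    td <- t[rel] - t2
    y[rel] <- (e - o) * exp(-td / tau_fast) + o * exp(-td / tau_slow)
    y
  }
  hbo2 <- piecewise(slopes[[1]])
  hbr <- piecewise(slopes[[2]])

  noise <- if (noise_sd > 0) {
    with_seed(seed, list(stats::rnorm(n, 0, noise_sd),
                         stats::rnorm(n, 0, noise_sd)))
  } else {
    list(numeric(n), numeric(n))
  }

  hbo2_m <- matrix(hbo2 + noise[[1]], ncol = 1,
                   dimnames = list(NULL, "forearm"))
  hbr_m <- matrix(hbr + noise[[2]], ncol = 1,
                  dimnames = list(NULL, "forearm"))
  structure(list(
    hemo = new_hemo_series(t, fs, hbo2_m, hbr_m, "forearm"),
    truth = list(hbo2 = matrix(hbo2, ncol = 1), hbr = matrix(hbr, ncol = 1)),
    schedule = NULL, fs = fs,
    params = list(durations = durations, slopes = slopes,
                  overshoot_frac = overshoot_frac, tau_fast = tau_fast,
                  tau_slow = tau_slow,
                  phase_times = c(t1 = t1, t2 = t2, t3 = t3)),
    artifact_log = data.frame(type = character(0), time = numeric(0),
                              amplitude = numeric(0)),
    seed = seed
  ), class = "hemo_sim")
}
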
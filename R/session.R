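#' Session configuration
#'
#' Collects every tunable of the simulated dual-modal session. Defaults
#' reproduce the standard patch protocol: 1 kHz EEG and 100 Hz fNIRS
#' sampling, 30 trials (one third congruent) displayed for 500 ms with
#' 350-750 ms inter-stimulus intervals, epochs from -250 to +750 ms,
#' 0.8-17 Hz ERP band, third-order 0.01-0.08 Hz haemodynamic band-pass,
#' 50 Hz front-end low-pass with x1000 gain, and an LED switching
#' frequency above 100 Hz.
#'
#' @param eeg_fs,fnirs_fs sampling rates, Hz.
#' @param n_trials,congruent_fraction,display_s,isi_low_s,isi_high_s,wait_s,rest_s
#'   schedule parameters, see [make_stroop_schedule()].
#' @param amp_hbo2 peak evoked HbO2 change, uM (HbR is -25 percent of it).
#' @param noise_cfg physiological-noise settings, [physio_noise_cfg()].
#' @param spike_times,spike_amps,shift_times,shift_amps motion artifacts to
#'   inject, see [inject_motion_artifacts()].
#' @param erp_targets nominal component window means, uV.
#' @param background_cfg EEG background, [eeg_background_cfg()].
#' @param erp_window,erp_band,erp_order epoching window and ERP band-pass.
#' @param hemo_band,hemo_order haemodynamic band-pass.
#' @param lpf_cutoff,gain,chain_noise_rms acquisition-chain model.
#' @param f_switch,crosstalk_amp LED switching crosstalk injection.
#' @param participant_sd between-session scale of the shared neurovascular
#'   responsiveness factor (couples ERP and haemodynamic amplitudes across
#'   virtual participants).
#' @param geometry optode geometry, [optode_geometry()].
#' @return a `session_config` list.
#' @export
session_config <- function(eeg_fs = 1000, fnirs_fs = 100, n_trials = 30,
                           congruent_fraction = 1 / 3, display_s = 0.5,
                           isi_low_s = 0.35, isi_high_s = 0.75,
                           wait_s = 30, rest_s = 60, amp_hbo2 = 0.5,
                           noise_cfg = physio_noise_cfg(),
                           spike_times = numeric(0), spike_amps = numeric(0),
                           shift_times = numeric(0), shift_amps = numeric(0),
                           erp_targets = c(P450 = -2.7, N500 = -4.0,
                                           P600 = -2.0),
                           background_cfg = eeg_background_cfg(),
                           erp_window = c(-0.25, 0.75), erp_band = c(0.8, 17),
                           erp_order = 4, hemo_band = c(0.01, 0.08),
                           hemo_order = 3, lpf_cutoff = 50, gain = 1000,
                           chain_noise_rms = 0.8, f_switch = 125,
                           crosstalk_amp = 0, participant_sd = 0.15,
                           geometry = optode_geometry()) {
  cfg <- as.list(environment())
  class(cfg) <- "session_config"
  cfg
}

sub_seed <- function(seed, offset) {
  (abs(seed) * 7919 + offset) %% 2147483647
}

#' Run one simulated Stroop session end to end
#'
#' Executes the full pipeline on synthetic data: event schedule ->
#' ground-truth haemodynamics (+ motion artifacts) -> forward optics ->
#' optical density -> modified Beer-Lambert inversion -> cleaning chain ->
#' response peaks, in parallel with ERP-template EEG (+ crosstalk) ->
#' acquisition chain -> epoching -> baseline correction -> averaged ERP
#' components. Every stage's output is retained in the returned bundle; a
#' manifest with the configuration, seeds and a reproducibility hash is
#' attached.
#'
#' @param config a [session_config()].
#' @param seed integer session seed; all stage seeds derive from it.
#' @param out_dir optional directory; when given, intermediates are
#'   persisted as CSV/TSV/JSON.
#' @param participant_gain responsiveness multiplier applied to both the
#'   evoked haemodynamic and ERP amplitudes (1 = nominal).
#' @return a `stroop_session` list: `schedule`, `sim` (haemodynamic ground
#'   truth), `raw_optical`, `hemo_recovered`, `hemo_clean`, `clean_report`,
#'   `peaks`, `eeg`, `erp`, `components`, `manifest`.
#' @export
run_stroop_session <- function(config = session_config(), seed,
                               out_dir = NULL, participant_gain = 1) {
  stage <- "schedule"
  bundle <- tryCatch({
    schedule <- make_stroop_schedule(
      n_trials = config$n_trials,
      congruent_fraction = config$congruent_fraction,
      display_s = config$display_s, isi_low_s = config$isi_low_s,
      isi_high_s = config$isi_high_s, wait_s = config$wait_s,
      rest_s = config$rest_s, seed = sub_seed(seed, 1))

    stage <- "synthgen-hemo"
    sim <- simulate_hemodynamics(
      schedule, fs = config$fnirs_fs,
      amp_hbo2 = participant_gain * config$amp_hbo2,
      noise_cfg = config$noise_cfg,
      channels = config$geometry$channels, seed = sub_seed(seed, 2))
    sim <- inject_motion_artifacts(
      sim, spike_times = config$spike_times, spike_amps = config$spike_amps,
      shift_times = config$shift_times, shift_amps = config$shift_amps)

    stage <- "forward-optics"
    raw <- forward_mbll(sim$hemo, config$geometry)

    stage <- "mbll"
    od <- optical_density(raw, baseline_window = c(0, config$wait_s))
    hemo_rec <- invert_mbll(od)

    stage <- "fnirs-clean"
    cleaned <- clean_fnirs(hemo_rec, band = config$hemo_band,
                           order = config$hemo_order)

    stage <- "peaks"
    peaks <- extract_response_peaks(cleaned$hemo,
                                    schedule$period_boundaries)

    stage <- "synthgen-eeg"
    tpl <- make_erp_template(targets = participant_gain * config$erp_targets,
                             fs = config$eeg_fs, window = config$erp_window,
                             band = config$erp_band,
                             band_order = config$erp_order)
    eeg <- simulate_eeg(schedule, fs = config$eeg_fs, erp_templates = tpl,
                        background_cfg = config$background_cfg,
                        channels = config$geometry$channels,
                        seed = sub_seed(seed, 3))
    if (config$crosstalk_amp > 0) {
      eeg <- inject_crosstalk(eeg, config$f_switch, config$crosstalk_amp)
    }

    stage <- "eeg-erp"
    eeg_acq <- acquisition_chain(eeg, gain = config$gain,
                                 lpf_cutoff = config$lpf_cutoff,
                                 noise_rms = config$chain_noise_rms,
                                 seed = sub_seed(seed, 4))
    epochs <- baseline_correct(epoch_eeg(eeg_acq, window = config$erp_window))
    erp <- average_erp(epochs, band = config$erp_band,
                       order = config$erp_order)

    list(schedule = schedule, sim = sim, raw_optical = raw,
         hemo_recovered = hemo_rec, hemo_clean = cleaned$hemo,
         clean_report = cleaned$report, peaks = peaks, eeg = eeg,
         erp = erp, components = erp$components)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  manifest <- list(
    package = "fnirseeg",
    version = as.character(utils::packageVersion("fnirseeg")),
    seed = seed,
    participant_gain = participant_gain,
    config_hash = rlang::hash(unclass(config)),
    n_trials_epoched = bundle$erp$n_trials,
    output_hash = rlang::hash(list(bundle$hemo_clean$hbo2,
                                   bundle$hemo_clean$hbr,
                                   bundle$erp$erp, bundle$components))
  )
  manifest$manifest_hash <- rlang::hash(manifest)
  bundle$manifest <- manifest

  if (!is.null(out_dir)) persist_session(bundle, out_dir)
  class(bundle) <- "stroop_session"
  bundle
}

persist_session <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events_tsv(bundle$schedule, file.path(out_dir, "events.tsv"))
  write_optical_csv(bundle$raw_optical, file.path(out_dir, "optical_raw.csv"))
  write_hemo_csv(bundle$hemo_recovered, file.path(out_dir, "hemo_mbll.csv"))
  write_hemo_csv(bundle$hemo_clean, file.path(out_dir, "hemo_clean.csv"))
  write_eeg_csv(bundle$eeg, file.path(out_dir, "eeg_raw.csv"))
  erp_df <- cbind(data.frame(time = bundle$erp$rel_time),
                  as.data.frame(bundle$erp$erp))
  write_table9(erp_df, file.path(out_dir, "erp_waveform.csv"), ",")
  write_report_json(bundle$clean_report,
                    file.path(out_dir, "cleaning_report.json"))
  write_report_json(list(components = as.data.frame(bundle$components)),
                    file.path(out_dir, "erp_components.json"))
  write_report_json(bundle$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Run a multi-session Stroop study with coupling statistics
#'
#' Simulates `n_participants` sessions (each with its own seed and a
#' shared-responsiveness factor scaling both the evoked haemodynamics and
#' the ERP templates), then computes the electro-vascular coupling: Pearson
#' correlation between each component's amplitude and the first/second HbR
#' peak values across sessions, and the paired Fp1-vs-Fp2 component
#' comparison.
#'
#' @param config a [session_config()].
#' @param n_participants number of virtual participants (sessions).
#' @param seed study seed.
#' @return a `stroop_study` list: `sessions` (bundles), `components`
#'   (session x component x channel), `hbr_peaks`, `coupling` (list of
#'   `coupling_result`), `channel_tests`, `manifest`.
#' @export
run_stroop_study <- function(config = session_config(), n_participants = 13,
                             seed) {
  gains <- with_seed(sub_seed(seed, 99), {
    pmax(0.2, stats::rnorm(n_participants, 1, config$participant_sd))
  })
  sessions <- lapply(seq_len(n_participants), function(i) {
    run_stroop_session(config, seed = sub_seed(seed, 1000 + i),
                       participant_gain = gains[i])
  })

  comp_names <- rownames(sessions[[1]]$components)
  chans <- colnames(sessions[[1]]$components)
  components <- array(
    vapply(sessions, function(s) s$components,
           matrix(0, length(comp_names), length(chans))),
    c(length(comp_names), length(chans), n_participants),
    dimnames = list(comp_names, chans, NULL))

  hbr_peaks <- t(vapply(sessions, function(s) {
    pk <- s$peaks$hbr
    c(first = first_signed_peak(pk, 1), second = first_signed_peak(pk, 2))
  }, c(first = 0, second = 0)))

  coupling <- list()
  for (cn in comp_names) {
    for (which_pk in c("first", "second")) {
      y <- hbr_peaks[, which_pk]
      if (all(is.finite(y)) && stats::sd(y) > 0) {
        coupling[[paste0(cn, "_Fp1_vs_hbr_", which_pk)]] <-
          pearson_coupling(components[cn, 1, ], y)
      }
    }
  }

  channel_tests <- lapply(stats::setNames(comp_names, comp_names),
                          function(cn) {
    paired_channel_comparison(components[cn, 1, ], components[cn, 2, ])
  })

  manifest <- list(
    package = "fnirseeg",
    version = as.character(utils::packageVersion("fnirseeg")),
    seed = seed, n_participants = n_participants,
    config_hash = rlang::hash(unclass(config)),
    session_hashes = vapply(sessions,
                            function(s) s$manifest$manifest_hash,
                            character(1))
  )
  manifest$manifest_hash <- rlang::hash(manifest)

  structure(list(sessions = sessions, components = components,
                 hbr_peaks = hbr_peaks, coupling = coupling,
                 channel_tests = channel_tests, manifest = manifest),
            class = "stroop_study")
}

# value of the n-th HbR peak regardless of sign convention: HbR responses
# are negative-going, so "peaks" are the successive minima; fall back to
# maxima if no minima qualify
first_signed_peak <- function(pk, n) {
  v <- nth_peak(pk, n, "min")
  if (is.na(v)) v <- nth_peak(pk, n, "max")
  v
}

#' Run the forearm arterial-occlusion experiment
#'
#' Simulates the cuff-occlusion trace, maps it through the forward optics,
#' inverts the modified Beer-Lambert law, and detrends (no task band-pass:
#' the occlusion response is not an event-related signal). Returns the
#' recovered and ground-truth series plus summary shape statistics.
#'
#' @param durations,slopes,overshoot_frac,tau_fast,tau_slow,fs,noise_sd
#'   forwarded to [simulate_forearm_block()].
#' @param detrend apply first-order detrending to the recovered series.
#' @param geometry optode geometry.
#' @param seed integer seed.
#' @return a `forearm_block` list: `sim`, `raw_optical`, `recovered`
#'   (detrended if requested), `truth`, `params`, `manifest`.
#' @export
run_forearm_block <- function(durations = c(baseline = 30, occlusion = 60,
                                            recovery = 90),
                              slopes = c(hbo2 = -0.1, hbr = 0.05),
                              overshoot_frac = 0.5, tau_fast = 2,
                              tau_slow = 15, fs = 100, noise_sd = 0.02,
                              detrend = TRUE,
                              geometry = optode_geometry("forearm"),
                              seed) {
  sim <- simulate_forearm_block(durations, slopes, overshoot_frac,
                                tau_fast, tau_slow, fs, noise_sd, seed)
  raw <- forward_mbll(sim$hemo, geometry)
  od <- optical_density(raw, i0 = raw$i0)
  rec <- invert_mbll(od)
  if (detrend) rec <- detrend_poly1(rec)
  manifest <- list(package = "fnirseeg",
                   version = as.character(utils::packageVersion("fnirseeg")),
                   seed = seed,
                   output_hash = rlang::hash(list(rec$hbo2, rec$hbr)))
  manifest$manifest_hash <- rlang::hash(manifest)
  structure(list(sim = sim, raw_optical = raw, recovered = rec,
                 truth = sim$truth, params = sim$params,
                 manifest = manifest),
            class = "forearm_block")
}
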
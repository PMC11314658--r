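# fnirseeg

Simulation and analysis of **co-located EEG-fNIRS recordings** — the kind
produced by wearable prefrontal patches that place EEG electrodes (Fp1/Fp2)
between the sources and detectors of a dual-wavelength (760/850 nm)
near-infrared optode array.

The package is written for researchers who need a fully verifiable version
of the standard dual-modal analysis chain. Every input the chain consumes
can be generated synthetically with ground truth retained, so each stage is
testable against known answers:

- **Synthetic acquisition** — Stroop-style event schedules (30 trials,
  500 ms display, 350–750 ms ISI), canonical double-gamma haemodynamic
  responses with Mayer-wave/respiratory/cardiac noise and drift, spike and
  baseline-shift motion artifacts, forward modified Beer-Lambert optics,
  ERP templates embedded in 1/f EEG background, LED time-division-
  multiplexing crosstalk, and a forearm cuff-occlusion scenario.
- **MBLL inversion** — optical density `ΔOD(λ,t) = −log10(I/I0)` and the
  per-sample 2×2 solve of
  `ΔOD(λ)/(d·DPF(λ)) = ε_HbO2(λ)·ΔHbO2 + ε_HbR(λ)·ΔHbR`
  for oxy-/deoxy-/total haemoglobin concentration changes (µM).
- **fNIRS cleaning** — first-order polynomial detrending, TDDR
  (temporal derivative distribution repair: Tukey-biweight reweighting of
  the temporal derivative, c = 4.685) and a third-order 0.01–0.08 Hz
  zero-phase Butterworth band-pass, implemented in numerically stable
  second-order sections.
- **EEG/ERP** — a model of the acquisition front end (50 Hz active
  low-pass, ×1000 gain, input-referred noise), epoching −250..+750 ms,
  baseline correction, trial averaging, 0.8–17 Hz zero-phase filtering,
  and signed window-mean amplitudes of the P450 (400–450 ms),
  N500 (450–550 ms) and P600 (600–700 ms) components.
- **Quality metrics** — input-referred noise, amplitude and frequency
  distortion, and the crosstalk residual ratio that quantifies why LED
  switching above 100 Hz separates cleanly from the 0–50 Hz EEG band.
- **Coupling statistics** — Pearson correlation between ERP component
  amplitudes and ΔHbR peak values across sessions, and the Fp1-vs-Fp2
  repeated-measures comparison via its exact paired-t equivalence
  (F = t²).

See `vignettes/colocated-eeg-fnirs-pipeline.Rmd` for the models,
parameter choices and numerical design decisions.

## Worked example

```r
library(fnirseeg)

# one full simulated Stroop session: schedule -> haemodynamics (+ artifacts)
# -> forward optics -> MBLL inversion -> cleaning -> peaks, in parallel with
# EEG synthesis -> acquisition chain -> epoching -> averaged ERP
session <- run_stroop_session(session_config(), seed = 1)
session$erp
#> <erp_result> 30 trials averaged, channels: Fp1, Fp2
#>         Fp1    Fp2
#> P450  0.150 -0.762
#> N500 -3.961 -4.467
#> P600 -1.892 -1.158
```

The matrix holds the signed mean amplitude (µV) of each component per
channel; with the default templates (window means −2.7/−4.0/−2.0 µV) a
30-trial average still carries a few µV of residual background, which is
why multi-session studies and 160-trial convergence checks exist.

```r
head(session$peaks$hbr, 2)      # ΔHbR extrema (µM) in the task+rest window
#>    time       value type
#> 5 42.82 -0.05533527  min
#> 1 48.26 -0.03328760  max

quality_report(duration_s = 120, noise_rms = 0.8, seed = 1)
#> <quality_report>
#>   input-referred noise     0.8020 uV RMS
#>   amplitude distortion     0.0778 %
#>   frequency distortion     0.0001 %
#>   crosstalk residual       0.0154 % (rejection 76.2 dB)
```

The noise metric recovers the 0.8 µV RMS injected into the simulated
chain; distortion of a 10 Hz / 100 µV test tone through the 50 Hz
front end is far below the 2% / 1% bounds expected of a usable chain; and
10 µV of 125 Hz switching crosstalk leaves essentially nothing inside the
EEG band.

```r
study <- run_stroop_study(session_config(n_trials = 10, wait_s = 15,
                                         rest_s = 30),
                          n_participants = 13, seed = 1)
study$coupling$N500_Fp1_vs_hbr_first
#> <coupling_result> r = 0.292, p = 0.3323, n = 13 (y = -0.0692 + 0.00367 x)
```

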
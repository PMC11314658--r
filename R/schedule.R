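#' Generate a Stroop-style event schedule
#'
#' Builds the trial timing for an event-related colour-word Stroop session:
#' a waiting (baseline) period, a task period of `n_trials` stimuli each
#' displayed for `display_s` seconds and separated by an inter-stimulus
#' interval drawn uniformly from `[isi_low_s, isi_high_s]`, and a rest
#' period. One third of trials are congruent by default, assigned in
#' uniformly random order.
#'
#' @param n_trials number of trials (>= 0).
#' @param congruent_fraction fraction of congruent trials in `[0, 1]`;
#'   fractional counts are rounded up (toward congruent).
#' @param display_s stimulus display duration in seconds.
#' @param isi_low_s,isi_high_s inter-stimulus interval bounds in seconds.
#' @param wait_s waiting-period duration before the first trial, seconds.
#' @param rest_s rest-period duration after the task, seconds.
#' @param seed integer seed; the schedule is a pure function of its arguments.
#' @return an object of class `event_schedule` with fields `onsets`,
#'   `conditions` (`"congruent"`/`"incongruent"`), `display_s`, `isi_bounds`,
#'   `period_boundaries` (start of waiting, task, rest, and session end) and
#'   `seed`.
#' @examples
#' sch <- make_stroop_schedule(seed = 1)
#' table(sch$conditions)
#' range(diff(sch$onsets))
#' @export
make_stroop_schedule <- function(n_trials = 30, congruent_fraction = 1 / 3,
                                 display_s = 0.5, isi_low_s = 0.35,
                                 isi_high_s = 0.75, wait_s = 30, rest_s = 60,
                                 seed) {
  if (n_trials < 0 || n_trials != round(n_trials)) {
    abort_fnirseeg("`n_trials` must be a non-negative integer",
                   "invalid_parameter")
  }
  if (congruent_fraction < 0 || congruent_fraction > 1) {
    abort_fnirseeg("`congruent_fraction` must be in [0, 1]",
                   "invalid_parameter")
  }
  if (display_s < 0 || isi_low_s < 0 || wait_s < 0 || rest_s < 0) {
    abort_fnirseeg("durations must be non-negative", "invalid_parameter")
  }
  if (isi_low_s > isi_high_s) {
    abort_fnirseeg("`isi_low_s` must be <= `isi_high_s`", "invalid_parameter")
  }

  nf <- n_trials * congruent_fraction
  n_cong <- if (abs(nf - round(nf)) < 1e-9) round(nf) else ceiling(nf)

  out <- with_seed(seed, {
    if (n_trials == 0) {
      list(onsets = numeric(0), conditions = character(0))
    } else {
      isi <- stats::runif(n_trials - 1, isi_low_s, isi_high_s)
      onsets <- wait_s + c(0, cumsum(display_s + isi))
      conds <- sample(rep(c("congruent", "incongruent"),
                          c(n_cong, n_trials - n_cong)))
      list(onsets = onsets, conditions = conds)
    }
  })

  task_end <- if (n_trials == 0) wait_s else out$onsets[n_trials] + display_s
  structure(list(
    onsets = out$onsets,
    conditions = out$conditions,
    display_s = display_s,
    isi_bounds = c(isi_low_s, isi_high_s),
    period_boundaries = c(waiting = 0, task = wait_s, rest = task_end,
                          end = task_end + rest_s),
    seed = seed
  ), class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf(
    "<event_schedule> %d trials (%d congruent), display %.3g s, ISI [%.3g, %.3g] s\n",
    length(x$onsets), sum(x$conditions == "congruent"), x$display_s,
    x$isi_bounds[1], x$isi_bounds[2]))
  cat(sprintf("  periods: waiting 0-%.4g s | task %.4g-%.4g s | rest %.4g-%.4g s\n",
              x$period_boundaries[2], x$period_boundaries[2],
              x$period_boundaries[3], x$period_boundaries[3],
              x$period_boundaries[4]))
  invisible(x)
}

session_duration <- function(schedule) {
  unname(schedule$period_boundaries[4])
}
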
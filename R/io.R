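# Plain-text readers/writers. CSV is the canonical interchange format
# (one time column + one column per channel/quantity); events use a
# BIDS-style TSV (onset, duration, trial_type); reports are JSON.
# Numeric values are written with 9 significant digits, which round-trips
# within the package's stated precision.

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

write_table9 <- function(df, path, sep) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write / read a haemodynamic series as CSV
#'
#' Columns: `time`, then `hbo2_<ch>`, `hbr_<ch>`, `hbt_<ch>` per channel,
#' micromolar.
#'
#' @param hemo a `hemo_series`.
#' @param path output file.
#' @return `write_hemo_csv` returns `path` invisibly; `read_hemo_csv`
#'   returns a `hemo_series`.
#' @export
write_hemo_csv <- function(hemo, path) {
  df <- data.frame(time = hemo$time)
  for (ch in hemo$channels) {
    df[[paste0("hbo2_", ch)]] <- hemo$hbo2[, ch]
    df[[paste0("hbr_", ch)]] <- hemo$hbr[, ch]
    df[[paste0("hbt_", ch)]] <- hemo$hbt[, ch]
  }
  write_table9(df, path, ",")
  invisible(path)
}

#' @rdname write_hemo_csv
#' @export
read_hemo_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  chans <- unique(sub("^hbo2_", "", grep("^hbo2_", names(df), value = TRUE)))
  fs <- 1 / stats::median(diff(df$time))
  hbo2 <- as.matrix(df[paste0("hbo2_", chans)])
  hbr <- as.matrix(df[paste0("hbr_", chans)])
  colnames(hbo2) <- colnames(hbr) <- chans
  new_hemo_series(df$time, fs, hbo2, hbr, chans)
}

#' Write / read raw dual-wavelength optical intensities as CSV
#'
#' Columns: `time`, then `<ch>_wl<lambda>` per channel and wavelength.
#' Geometry is not stored in the CSV; supply it when reading.
#'
#' @param raw a `raw_optical` recording.
#' @param path output file.
#' @param geometry an [optode_geometry()] used to rebuild the recording.
#' @return `write_optical_csv` returns `path` invisibly; `read_optical_csv`
#'   returns a `raw_optical`.
#' @export
write_optical_csv <- function(raw, path) {
  df <- data.frame(time = raw$time)
  wl <- raw$geometry$wavelengths
  for (ch in seq_along(raw$channels)) {
    for (w in 1:2) {
      df[[paste0(raw$channels[ch], "_wl", wl[w])]] <- raw$intensity[, ch, w]
    }
  }
  write_table9(df, path, ",")
  invisible(path)
}

#' @rdname write_optical_csv
#' @export
read_optical_csv <- function(path, geometry = optode_geometry()) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- geometry$wavelengths
  cols <- setdiff(names(df), "time")
  chans <- unique(sub(paste0("_wl(", wl[1], "|", wl[2], ")$"), "", cols))
  fs <- 1 / stats::median(diff(df$time))
  inten <- array(NA_real_, c(nrow(df), length(chans), 2),
                 dimnames = list(NULL, chans, paste0("wl", wl)))
  for (ch in seq_along(chans)) {
    for (w in 1:2) inten[, ch, w] <- df[[paste0(chans[ch], "_wl", wl[w])]]
  }
  structure(list(time = df$time, fs = fs, intensity = inten,
                 geometry = geometry, channels = chans,
                 i0 = NULL, baseline_window = c(0, 10)),
            class = "raw_optical")
}

#' Write / read an EEG recording as CSV
#'
#' Columns: `time` plus one microvolt column per channel. Events travel
#' separately via [write_events_tsv()].
#'
#' @param eeg an `eeg_recording`.
#' @param path output file.
#' @param events optional events data frame attached on read.
#' @return `write_eeg_csv` returns `path` invisibly; `read_eeg_csv` an
#'   `eeg_recording`.
#' @export
write_eeg_csv <- function(eeg, path) {
  df <- cbind(data.frame(time = (seq_len(nrow(eeg$samples)) - 1) / eeg$fs),
              as.data.frame(eeg$samples))
  write_table9(df, path, ",")
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path, events = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  fs <- 1 / stats::median(diff(df$time))
  m <- as.matrix(df[setdiff(names(df), "time")])
  if (is.null(events)) {
    events <- data.frame(onset = numeric(0), condition = character(0))
  }
  new_eeg_recording(m, fs, colnames(m), events)
}

#' Write / read an event schedule as BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type`; events are half-open
#' `[onset, onset + duration)` intervals in seconds from session start.
#'
#' @param schedule an `event_schedule` (or any data frame with onsets and
#'   conditions).
#' @param path output file.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   a data frame with `onset`, `duration`, `trial_type`.
#' @export
write_events_tsv <- function(schedule, path) {
  df <- data.frame(onset = schedule$onsets,
                   duration = rep(schedule$display_s,
                                  length(schedule$onsets)),
                   trial_type = schedule$conditions)
  write_table9(df, path, "\t")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path)
}

#' Write a report object as JSON
#'
#' @param x a report-like list (`cleaning_report`, `quality_report`,
#'   `coupling_result`, manifest, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
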
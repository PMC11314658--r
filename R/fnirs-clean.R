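#' First-order polynomial detrending
#'
#' Subtracts the least-squares line fitted over the full record from each
#' channel, removing linear baseline drift.
#'
#' @param x numeric vector, matrix (time x channel) or `hemo_series`.
#' @param fs sampling rate (required for plain numeric input without a time
#'   axis; used only to report slope per second).
#' @return for numeric input, a list `series` + `trend_coef` (intercept and
#'   slope per channel); for a `hemo_series`, the detrended series with a
#'   `trend_coef` attribute holding coefficients for both chromophores.
#' @export
detrend_poly1 <- function(x, fs = NULL) {
  if (inherits(x, "hemo_series")) {
    o <- detrend_mat(x$hbo2, x$time)
    r <- detrend_mat(x$hbr, x$time)
    out <- new_hemo_series(x$time, x$fs, o$series, r$series, x$channels)
    attr(out, "trend_coef") <- list(hbo2 = o$coef, hbr = r$coef)
    return(out)
  }
  v <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(v) < 2) {
    abort_fnirseeg("detrending needs at least 2 samples", "invalid_parameter")
  }
  t <- if (is.null(fs)) seq_len(nrow(v)) - 1 else (seq_len(nrow(v)) - 1) / fs
  res <- detrend_mat(v, t)
  if (!is.matrix(x)) res$series <- drop(res$series)
  list(series = res$series, trend_coef = res$coef)
}

detrend_mat <- function(v, t) {
  if (nrow(v) < 2) {
    abort_fnirseeg("detrending needs at least 2 samples", "invalid_parameter")
  }
  X <- cbind(1, t)
  coef <- qr.solve(X, v)
  list(series = v - X %*% coef,
       coef = matrix(coef, nrow = 2,
                     dimnames = list(c("intercept", "slope"), colnames(v))))
}

#' Temporal derivative distribution repair (TDDR) motion correction
#'
#' Removes spike artifacts and baseline shifts by robustly reweighting the
#' temporal derivative of the signal's low-frequency part. Following the
#' original formulation: the signal is split at 0.5 Hz into a
#' low-frequency part and a fluctuation; the first differences of the
#' low-frequency part are iteratively reweighted with Tukey's biweight
#' (tuning constant 4.685, scale 1.4826 x MAD) until the weight vector is
#' stable; the reweighted, centred derivatives are re-integrated and the
#' untouched fluctuation added back. Samples inside large transients
#' receive weights near zero.
#'
#' @param x numeric vector, matrix (time x channel) or `hemo_series`.
#' @param fs sampling rate, Hz (taken from a `hemo_series`).
#' @param tune Tukey biweight tuning constant.
#' @param tol convergence tolerance on the maximum weight change.
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE` and a warning.
#' @return for numeric input, a list with `series`, `weights` (one per
#'   derivative sample, in `[0, 1]`), `iterations`, `converged`; for a
#'   `hemo_series`, the corrected series with a `tddr_report` attribute.
#' @export
tddr <- function(x, fs = NULL, tune = 4.685, tol = 1e-6, max_iter = 50) {
  if (inherits(x, "hemo_series")) {
    o <- tddr(x$hbo2, x$fs, tune, tol, max_iter)
    r <- tddr(x$hbr, x$fs, tune, tol, max_iter)
    out <- new_hemo_series(x$time, x$fs, o$series, r$series, x$channels)
    attr(out, "tddr_report") <- list(
      weights = list(hbo2 = o$weights, hbr = r$weights),
      iterations = max(o$iterations, r$iterations),
      converged = o$converged && r$converged)
    return(out)
  }
  if (is.null(fs)) abort_fnirseeg("`fs` is required", "invalid_parameter")
  check_positive(fs, "fs")
  v <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(v) < 3) {
    abort_fnirseeg("TDDR needs at least 3 samples", "invalid_parameter")
  }
  W <- matrix(NA_real_, nrow(v) - 1, ncol(v))
  iters <- 0L; conv <- TRUE
  for (j in seq_len(ncol(v))) {
    res <- tddr_channel(v[, j], fs, tune, tol, max_iter)
    v[, j] <- res$series
    W[, j] <- res$weights
    iters <- max(iters, res$iterations)
    conv <- conv && res$converged
  }
  if (!conv) {
    warn_fnirseeg("TDDR weight iteration did not converge; returning best iterate",
                  "nonconvergence")
  }
  list(series = if (is.matrix(x)) v else drop(v),
       weights = if (is.matrix(x)) W else drop(W),
       iterations = iters, converged = conv)
}

tddr_channel <- function(sig, fs, tune, tol, max_iter) {
  wn <- 0.5 * 2 / fs
  if (wn < 1) {
    lp <- butter_sos(3, 0.5, fs, "low")
    low <- sos_filtfilt(lp, sig)
  } else {
    low <- sig
  }
  high <- sig - low

  d <- diff(low)
  w <- rep(1, length(d))
  iter <- 0L
  converged <- FALSE
  mu <- 0
  repeat {
    iter <- iter + 1L
    mu <- sum(w * d) / sum(w)
    dev <- abs(d - mu)
    sigma <- 1.4826 * stats::median(dev)
    if (sigma <= .Machine$double.eps * max(abs(d), 1)) {
      w_new <- rep(1, length(d))  # derivative essentially constant: keep all
      converged <- TRUE
      w <- w_new
      break
    }
    r <- dev / (sigma * tune)
    w_new <- ((1 - r^2) * (r < 1))^2
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
    if (iter >= max_iter) break
  }
  # centred re-integration: concentration-change series are referenced to
  # an arbitrary baseline, so the (artifact-contaminated) mean is dropped
  corrected <- cumsum(c(0, w * (d - mu)))
  corrected <- corrected - mean(corrected)
  list(series = corrected + high, weights = w, iterations = iter,
       converged = converged)
}

#' Haemodynamic band-pass filter
#'
#' Zero-phase Butterworth band-pass isolating the task-evoked haemodynamic
#' band and rejecting physiological nuisance components (Mayer waves,
#' respiration, cardiac pulsation) and residual very-slow drift. Defaults
#' follow the standard event-related configuration: third order,
#' 0.01-0.08 Hz.
#'
#' @param x numeric vector, matrix or `hemo_series`.
#' @param fs sampling rate, Hz (taken from a `hemo_series`).
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order.
#' @return filtered series of the same shape/class, with a `filter_design`
#'   attribute recording order, nominal cutoffs and the realized single-pass
#'   -3 dB points.
#' @export
bandpass_hemo <- function(x, fs = NULL, low = 0.01, high = 0.08, order = 3) {
  if (inherits(x, "hemo_series")) {
    filt <- design_hemo_filter(low, high, order, x$fs)
    out <- new_hemo_series(x$time, x$fs,
                           sos_filtfilt(filt, x$hbo2),
                           sos_filtfilt(filt, x$hbr), x$channels)
    attr(out, "filter_design") <- filter_design_info(filt)
    return(out)
  }
  if (is.null(fs)) abort_fnirseeg("`fs` is required", "invalid_parameter")
  filt <- design_hemo_filter(low, high, order, fs)
  out <- sos_filtfilt(filt, x)
  attr(out, "filter_design") <- filter_design_info(filt)
  out
}

design_hemo_filter <- function(low, high, order, fs) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort_fnirseeg("band must satisfy 0 < low < high < fs/2",
                   "invalid_parameter")
  }
  butter_sos(order, c(low, high), fs, "pass")
}

filter_design_info <- function(filt) {
  target <- 1 / sqrt(2)
  lo3 <- tryCatch(stats::uniroot(function(f) filter_gain(filt, f) - target,
                                 c(filt$cutoff[1] / 10, mean(filt$cutoff)),
                                 tol = 1e-10)$root, error = function(e) NA)
  hi3 <- tryCatch(stats::uniroot(function(f) filter_gain(filt, f) - target,
                                 c(mean(filt$cutoff),
                                   min(filt$fs / 2 * 0.999,
                                       filt$cutoff[2] * 10)),
                                 tol = 1e-10)$root, error = function(e) NA)
  list(order = filt$order, cutoff = filt$cutoff, fs = filt$fs,
       realized_3db = c(low = lo3, high = hi3))
}

#' Run the fNIRS cleaning chain
#'
#' Applies, in the standard order, first-order polynomial detrending,
#' TDDR motion correction, and the 0.01-0.08 Hz third-order zero-phase
#' band-pass to a haemodynamic series. Each stage can be disabled.
#'
#' @param hemo a `hemo_series`.
#' @param detrend,motion_correct,bandpass logical stage switches.
#' @param band band-pass edges in Hz.
#' @param order band-pass Butterworth order.
#' @param tddr_tune,tddr_tol,tddr_max_iter TDDR parameters, see [tddr()].
#' @return list with the cleaned `hemo` and a `report` (class
#'   `cleaning_report`) holding trend coefficients, TDDR iteration/weight
#'   summary and filter design parameters.
#' @export
clean_fnirs <- function(hemo, detrend = TRUE, motion_correct = TRUE,
                        bandpass = TRUE, band = c(0.01, 0.08), order = 3,
                        tddr_tune = 4.685, tddr_tol = 1e-6,
                        tddr_max_iter = 50) {
  report <- list()
  out <- hemo
  if (detrend) {
    out <- detrend_poly1(out)
    report$trend_coef <- attr(out, "trend_coef")
  }
  if (motion_correct) {
    out <- tddr(out, tune = tddr_tune, tol = tddr_tol,
                max_iter = tddr_max_iter)
    rep_t <- attr(out, "tddr_report")
    report$tddr <- list(
      iterations = rep_t$iterations, converged = rep_t$converged,
      weight_summary = lapply(rep_t$weights, function(w) {
        c(min = min(w), mean = mean(w), frac_downweighted = mean(w < 0.5))
      }))
  }
  if (bandpass) {
    out <- bandpass_hemo(out, low = band[1], high = band[2], order = order)
    report$filter <- attr(out, "filter_design")
  }
  list(hemo = out, report = structure(report, class = "cleaning_report"))
}

#' Extract haemodynamic response peaks
#'
#' Finds local extrema of the cleaned concentration series inside the
#' task-plus-rest window, ordered by time. A peak is a local extremum whose
#' topographic prominence exceeds `min_prominence_frac` of the series range
#' (suppressing filter ripple); "first" and "second" peaks of a chromophore
#' are the first two extrema of the appropriate sign.
#'
#' @param hemo a `hemo_series` (typically after [clean_fnirs()]).
#' @param period_boundaries schedule period boundaries (waiting/task/rest
#'   edges in seconds); peaks are searched from task onset to session end.
#' @param channel channel label or index (default first channel).
#' @param min_prominence_frac prominence threshold as a fraction of range.
#' @return named list with data frames `hbo2` and `hbr`, columns `time`,
#'   `value`, `type` (`"max"`/`"min"`); empty when no extremum qualifies.
#' @export
extract_response_peaks <- function(hemo, period_boundaries,
                                   channel = 1, min_prominence_frac = 0.1) {
  t0 <- period_boundaries[[2]]
  t1 <- period_boundaries[[length(period_boundaries)]]
  sel <- hemo$time >= t0 & hemo$time <= t1
  if (!any(sel)) {
    abort_fnirseeg("task period lies outside the recording",
                   "invalid_parameter")
  }
  tt <- hemo$time[sel]
  lapply(list(hbo2 = hemo$hbo2, hbr = hemo$hbr), function(m) {
    x <- m[sel, channel]
    find_peaks(tt, x, min_prominence_frac)
  })
}

find_peaks <- function(t, x, min_prominence_frac) {
  n <- length(x)
  empty <- data.frame(time = numeric(0), value = numeric(0),
                      type = character(0))
  if (n < 3) return(empty)
  thresh <- min_prominence_frac * diff(range(x))
  if (thresh == 0) return(empty)
  rows <- list()
  dx <- diff(x)
  for (sign_dir in c(1, -1)) {
    y <- sign_dir * x
    idx <- which(diff(sign(diff(y))) < 0) + 1L  # strict local maxima of y
    for (i in idx) {
      lo_l <- min(y[1:i]); lo_r <- min(y[i:n])
      j_hi_l <- rev(which(y[1:(i - 1)] > y[i]))
      if (length(j_hi_l)) lo_l <- min(y[j_hi_l[1]:i])
      j_hi_r <- which(y[(i + 1):n] > y[i])
      if (length(j_hi_r)) lo_r <- min(y[i:(i + j_hi_r[1])])
      prom <- y[i] - max(lo_l, lo_r)
      if (prom >= thresh) {
        rows[[length(rows) + 1]] <- data.frame(
          time = t[i], value = x[i],
          type = if (sign_dir > 0) "max" else "min")
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}

#' Select the n-th peak of a given sign
#'
#' @param peaks a peak data frame from [extract_response_peaks()].
#' @param n which peak (1 = first, 2 = second, ...).
#' @param type `"max"` or `"min"`.
#' @return the peak value, or `NA` if fewer than `n` such peaks exist.
#' @export
nth_peak <- function(peaks, n = 1, type = c("max", "min")) {
  type <- match.arg(type)
  sel <- peaks[peaks$type == type, , drop = FALSE]
  if (nrow(sel) < n) return(NA_real_)
  sel$value[n]
}
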
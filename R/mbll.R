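#' Optode geometry for a dual-wavelength continuous-wave channel
#'
#' @param channels channel labels.
#' @param separation_mm source-detector separation in millimetres (> 0);
#'   30 mm is the standard adult-forehead configuration.
#' @param wavelengths the two LED wavelengths in nanometres.
#' @param dpf differential pathlength factor per wavelength (dimensionless).
#' @return object of class `optode_geometry`.
#' @export
optode_geometry <- function(channels = c("Fp1", "Fp2"), separation_mm = 30,
                            wavelengths = c(760, 850), dpf = c(6, 6)) {
  check_positive(separation_mm, "separation_mm")
  if (length(wavelengths) != 2 || wavelengths[1] == wavelengths[2]) {
    abort_fnirseeg("exactly two distinct wavelengths are required",
                   "invalid_parameter")
  }
  dpf <- rep_len(dpf, 2)
  if (any(dpf <= 0)) abort_fnirseeg("DPF must be > 0", "invalid_parameter")
  structure(list(channels = channels, separation_mm = separation_mm,
                 wavelengths = wavelengths, dpf = dpf),
            class = "optode_geometry")
}

#' Haemoglobin extinction coefficients at the patch wavelengths
#'
#' Molar extinction coefficients of oxy- and deoxy-haemoglobin at 760 and
#' 850 nm, in 1/(cm x mM), taken from the standard compiled in-vivo spectra
#' (Prahl compilation, Oregon Medical Laser Center) as packaged by the
#' common fNIRS processing toolboxes. Override with your own table to use a
#' different compendium or wavelength pair.
#'
#' @return data frame with columns `wavelength`, `hbo2`, `hbr` and a
#'   `source` attribute.
#' @export
extinction_defaults <- function() {
  tab <- data.frame(
    wavelength = c(760, 850),
    hbo2 = c(0.58600, 1.05800),
    hbr = c(1.54852, 0.69132)
  )
  attr(tab, "source") <-
    "Prahl compiled haemoglobin spectra, units 1/(cm*mM)"
  tab
}

# 2x2 extinction matrix for the geometry's wavelength pair, with an
# ill-conditioning guard (proportional rows make MBLL inversion impossible)
extinction_matrix <- function(coeffs, wavelengths) {
  rows <- match(wavelengths, coeffs$wavelength)
  if (anyNA(rows)) {
    abort_fnirseeg("extinction table lacks one of the requested wavelengths",
                   "invalid_parameter")
  }
  E <- rbind(c(coeffs$hbo2[rows[1]], coeffs$hbr[rows[1]]),
             c(coeffs$hbo2[rows[2]], coeffs$hbr[rows[2]]))
  sv <- svd(E)$d
  if (sv[2] <= 0 || sv[1] / sv[2] > 1e6) {
    abort_fnirseeg("extinction matrix is singular or ill-conditioned",
                   "ill_conditioned")
  }
  E
}

#' Construct a haemodynamic concentration-change series
#'
#' @param time time axis in seconds.
#' @param fs sampling rate, Hz.
#' @param hbo2,hbr micromolar concentration-change matrices (time x channel).
#' @param channels channel labels.
#' @return object of class `hemo_series`; `hbt` is `hbo2 + hbr` by
#'   definition.
#' @export
new_hemo_series <- function(time, fs, hbo2, hbr, channels = colnames(hbo2)) {
  hbo2 <- as.matrix(hbo2); hbr <- as.matrix(hbr)
  stopifnot(nrow(hbo2) == length(time), all(dim(hbo2) == dim(hbr)))
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(hbo2)))
  colnames(hbo2) <- colnames(hbr) <- channels
  structure(list(time = time, fs = fs, hbo2 = hbo2, hbr = hbr,
                 hbt = hbo2 + hbr, channels = channels),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("<hemo_series> %d samples @ %g Hz, channels: %s\n",
              length(x$time), x$fs, paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Forward modified Beer-Lambert model: concentrations to light intensity
#'
#' Maps concentration changes to detected dual-wavelength intensities:
#' `I(lambda, t) = i0(lambda) * 10^(-dOD(lambda, t))` with
#' `dOD = (eps_HbO2 * dHbO2 + eps_HbR * dHbR) * d * DPF(lambda)` (the
#' concentration-to-absorbance step of the modified Beer-Lambert law, run
#' in the generative direction).
#'
#' @param hemo a `hemo_series` (micromolar).
#' @param geom an [optode_geometry()].
#' @param coeffs extinction table, see [extinction_defaults()].
#' @param i0 baseline detected intensity per wavelength (arbitrary detector
#'   units, > 0).
#' @return object of class `raw_optical`: `intensity` array
#'   (time x channel x wavelength), `fs`, `geometry`, `i0`,
#'   `baseline_window`.
#' @export
forward_mbll <- function(hemo, geom = optode_geometry(hemo$channels),
                         coeffs = extinction_defaults(), i0 = c(1, 1)) {
  i0 <- rep_len(i0, 2)
  if (any(i0 <= 0)) abort_fnirseeg("`i0` must be > 0", "invalid_parameter")
  E <- extinction_matrix(coeffs, geom$wavelengths)
  d_cm <- geom$separation_mm / 10
  n <- length(hemo$time); nch <- ncol(hemo$hbo2)
  inten <- array(NA_real_, c(n, nch, 2),
                 dimnames = list(NULL, hemo$channels,
                                 paste0("wl", geom$wavelengths)))
  for (w in 1:2) {
    # concentrations are uM; extinction is per mM, hence the 1e-3
    od <- (E[w, 1] * hemo$hbo2 + E[w, 2] * hemo$hbr) * 1e-3 *
      d_cm * geom$dpf[w]
    inten[, , w] <- i0[w] * 10^(-od)
  }
  structure(list(time = hemo$time, fs = hemo$fs, intensity = inten,
                 geometry = geom, channels = hemo$channels, i0 = i0,
                 baseline_window = c(0, 10)),
            class = "raw_optical")
}

#' @export
print.raw_optical <- function(x, ...) {
  cat(sprintf(
    "<raw_optical> %d samples @ %g Hz, %d channel(s) x %d wavelengths (%s nm)\n",
    length(x$time), x$fs, length(x$channels), 2,
    paste(x$geometry$wavelengths, collapse = "/")))
  invisible(x)
}

#' Optical density change from raw intensities
#'
#' `dOD(lambda, t) = -log10(I(lambda, t) / I0(lambda))`, with the reference
#' intensity `I0` either supplied (e.g. the generator's true baseline) or
#' estimated as the mean intensity over a baseline window, conventionally
#' the waiting period at the start of the recording.
#'
#' @param raw a `raw_optical` recording (all intensities must be > 0).
#' @param baseline_window `c(start, end)` seconds used to estimate `I0`;
#'   defaults to the recording's stored window (first 10 s).
#' @param i0 optional known baseline intensity per wavelength, bypassing the
#'   window estimate.
#' @return object of class `od_series` with array `od`
#'   (time x channel x wavelength).
#' @export
optical_density <- function(raw, baseline_window = NULL, i0 = NULL) {
  if (any(raw$intensity <= 0)) {
    abort_fnirseeg("intensities must be strictly positive", "domain")
  }
  n <- length(raw$time); nch <- length(raw$channels)
  od <- array(NA_real_, dim(raw$intensity), dimnames = dimnames(raw$intensity))
  if (is.null(i0)) {
    if (is.null(baseline_window)) baseline_window <- raw$baseline_window
    sel <- raw$time >= baseline_window[1] & raw$time < baseline_window[2]
    if (!any(sel)) {
      abort_fnirseeg("baseline window contains no samples", "invalid_parameter")
    }
    for (w in 1:2) for (ch in seq_len(nch)) {
      od[, ch, w] <- -log10(raw$intensity[, ch, w] /
                              mean(raw$intensity[sel, ch, w]))
    }
  } else {
    i0 <- rep_len(i0, 2)
    for (w in 1:2) od[, , w] <- -log10(raw$intensity[, , w, drop = FALSE] / i0[w])
  }
  structure(list(time = raw$time, fs = raw$fs, od = od,
                 geometry = raw$geometry, channels = raw$channels),
            class = "od_series")
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and time point, the 2x2 linear system
#' `dOD(lambda) / (d * DPF(lambda)) = E %*% c(dHbO2, dHbR)` for the
#' chromophore concentration changes, and returns their sum as total
#' haemoglobin.
#'
#' @param od an `od_series` from [optical_density()].
#' @param geom optode geometry; defaults to the geometry carried by `od`.
#' @param coeffs extinction table.
#' @return a `hemo_series` in micromolar.
#' @export
invert_mbll <- function(od, geom = od$geometry,
                        coeffs = extinction_defaults()) {
  E <- extinction_matrix(coeffs, geom$wavelengths)
  Einv <- solve(E)
  d_cm <- geom$separation_mm / 10
  n <- length(od$time); nch <- length(od$channels)
  hbo2 <- matrix(NA_real_, n, nch, dimnames = list(NULL, od$channels))
  hbr <- hbo2
  for (ch in seq_len(nch)) {
    lhs <- rbind(od$od[, ch, 1] / (d_cm * geom$dpf[1]),
                 od$od[, ch, 2] / (d_cm * geom$dpf[2]))
    conc <- Einv %*% lhs  # mM
    hbo2[, ch] <- conc[1, ] * 1e3
    hbr[, ch] <- conc[2, ] * 1e3
  }
  new_hemo_series(od$time, od$fs, hbo2, hbr, od$channels)
}
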
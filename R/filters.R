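#' @useDynLib fnirseeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Design a Butterworth filter in second-order sections
#'
#' Designs a digital Butterworth filter by bilinear transform of the analog
#' prototype, keeping the design in zero-pole-gain form and factoring it into
#' cascaded biquads (second-order sections, SOS). The SOS form stays
#' numerically stable at the very small normalized cutoffs used in
#' haemodynamic-band filtering (e.g. 0.01 Hz at a 100 Hz sampling rate), where
#' expanded transfer-function polynomials are not.
#'
#' @param order filter order (of the analog prototype; a band-pass of order
#'   `n` has `2n` poles).
#' @param cutoff cutoff frequency in Hz; a length-2 vector `c(low, high)` for
#'   `type = "pass"`.
#' @param fs sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return an object of class `butter_sos` with elements `sos` (k x 6 matrix),
#'   `order`, `cutoff`, `fs`, `type`.
#' @examples
#' bp <- butter_sos(3, c(0.01, 0.08), fs = 100, type = "pass")
#' filter_gain(bp, 0.04)
#' @export
butter_sos <- function(order, cutoff, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (order < 1 || order != round(order)) {
    abort_fnirseeg("`order` must be a positive integer", "invalid_parameter")
  }
  if (fs <= 0) abort_fnirseeg("`fs` must be > 0", "invalid_parameter")
  nyq <- fs / 2
  if (any(cutoff <= 0) || any(cutoff >= nyq)) {
    abort_fnirseeg("cutoff frequencies must lie strictly inside (0, fs/2)",
                   "invalid_parameter")
  }
  if (type == "pass") {
    if (length(cutoff) != 2 || cutoff[1] >= cutoff[2]) {
      abort_fnirseeg("band-pass needs cutoff = c(low, high) with low < high",
                     "invalid_parameter")
    }
  } else if (length(cutoff) != 1) {
    abort_fnirseeg("low/high-pass take a single cutoff", "invalid_parameter")
  }

  # analog Butterworth prototype: unit-radius poles in the left half plane
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))

  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)  # bilinear pre-warp

  if (type == "low") {
    wc <- warp(cutoff)
    pa <- proto * wc
    za <- complex(0)
    ka <- wc^order
  } else if (type == "high") {
    wc <- warp(cutoff)
    pa <- wc / proto
    za <- rep(0 + 0i, order)
    ka <- 1
  } else {
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    b <- proto * bw / 2
    pa <- c(b + sqrt(b^2 - w0^2), b - sqrt(b^2 - w0^2))
    za <- rep(0 + 0i, order)
    ka <- bw^order
  }

  # bilinear transform to the z-plane
  pd <- (fs2 + pa) / (fs2 - pa)
  zd <- if (length(za)) (fs2 + za) / (fs2 - za) else complex(0)
  # zeros pushed from s = Inf land at z = -1
  zd <- c(zd, rep(-1 + 0i, length(pa) - length(za)))
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))

  sos <- zpk_to_sos(zd, pd, kd)
  structure(list(sos = sos, order = order, cutoff = cutoff, fs = fs,
                 type = type),
            class = "butter_sos")
}

# Factor digital zeros/poles/gain into second-order sections.
# Assumes zeros are real (Butterworth: all at +1 / -1) and poles occur in
# conjugate pairs or as reals; general enough for every design in the package.
zpk_to_sos <- function(z, p, k) {
  tol <- 1e-10
  cplx <- p[Im(p) > tol]
  realp <- Re(p[abs(Im(p)) <= tol])
  # most-damped poles first; the section nearest the unit circle runs last
  cplx <- cplx[order(abs(1 - Mod(cplx)), decreasing = TRUE)]
  realp <- sort(realp)

  zr <- Re(z)
  pos <- sort(zr[zr >= 0], decreasing = TRUE)  # zeros at/near +1
  neg <- sort(zr[zr < 0])                      # zeros at/near -1

  take_zero_pair <- function() {
    # prefer one +1 and one -1 zero per section (band-pass geometry);
    # fall back to whatever remains
    zz <- c()
    if (length(pos) > 0) { zz <- c(zz, pos[1]); pos <<- pos[-1] }
    if (length(neg) > 0) { zz <- c(zz, neg[1]); neg <<- neg[-1] }
    while (length(zz) < 2 && length(pos) > 0) { zz <- c(zz, pos[1]); pos <<- pos[-1] }
    while (length(zz) < 2 && length(neg) > 0) { zz <- c(zz, neg[1]); neg <<- neg[-1] }
    zz
  }

  rows <- list()
  for (pp in cplx) {
    a <- c(1, -2 * Re(pp), Mod(pp)^2)
    zz <- take_zero_pair()
    b <- if (length(zz) == 2) c(1, -(zz[1] + zz[2]), zz[1] * zz[2])
         else if (length(zz) == 1) c(1, -zz[1], 0)
         else c(1, 0, 0)
    rows[[length(rows) + 1]] <- c(b, a)
  }
  while (length(realp) >= 2) {
    p1 <- realp[1]; p2 <- realp[2]; realp <- realp[-(1:2)]
    a <- c(1, -(p1 + p2), p1 * p2)
    zz <- take_zero_pair()
    b <- if (length(zz) == 2) c(1, -(zz[1] + zz[2]), zz[1] * zz[2])
         else if (length(zz) == 1) c(1, -zz[1], 0)
         else c(1, 0, 0)
    rows[[length(rows) + 1]] <- c(b, a)
  }
  if (length(realp) == 1) {
    a <- c(1, -realp[1], 0)
    zz <- if (length(pos)) { v <- pos[1]; pos <- pos[-1]; v }
          else if (length(neg)) { v <- neg[1]; neg <- neg[-1]; v }
          else NULL
    b <- if (is.null(zz)) c(1, 0, 0) else c(1, -zz, 0)
    rows[[length(rows) + 1]] <- c(b, a)
  }
  sos <- do.call(rbind, rows)
  sos[1, 1:3] <- sos[1, 1:3] * k
  unname(sos)
}

# steady-state per-section initial conditions for a unit-amplitude step input
sos_zi <- function(sos) {
  ks <- nrow(sos)
  zi <- matrix(0, ks, 2)
  scale <- 1
  for (s in seq_len(ks)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    g <- sum(b) / sum(a)
    x <- scale; y <- scale * g
    zi[s, 1] <- (b[2] + b[3]) * x - (a[2] + a[3]) * y
    zi[s, 2] <- b[3] * x - a[3] * y
    scale <- y
  }
  zi
}

#' Apply a second-order-section filter
#'
#' Single-pass (causal) filtering with steady-state initial conditions
#' matched to the first sample, so a constant input produces a constant
#' output without a start-up transient.
#'
#' @param filt a `butter_sos` object.
#' @param x numeric vector or matrix (filtered column-wise).
#' @return filtered signal, same shape as `x`.
#' @export
sos_filter <- function(filt, x) {
  apply_cols(x, function(v) {
    zi <- sos_zi(filt$sos) * v[1]
    sosfilt_cpp(filt$sos, v, zi)
  })
}

#' Zero-phase (forward-backward) second-order-section filtering
#'
#' Applies the filter forward and backward, cancelling phase distortion and
#' squaring the magnitude response. The signal is extended by odd reflection
#' at both ends before filtering to suppress edge transients, and each pass
#' starts from steady-state initial conditions.
#'
#' @param filt a `butter_sos` object.
#' @param x numeric vector or matrix (filtered column-wise).
#' @param padlen reflection padding length in samples; defaults to three time
#'   constants of the slowest band edge, capped at `length(x) - 1`.
#' @return filtered signal, same shape as `x`.
#' @export
sos_filtfilt <- function(filt, x, padlen = NULL) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (is.null(padlen)) {
    slow <- min(filt$cutoff)
    padlen <- ceiling(3 * filt$fs / slow)
  }
  padlen <- max(3 * nrow(filt$sos), padlen)
  padlen <- min(n - 1, padlen)
  apply_cols(x, function(v) {
    pre <- 2 * v[1] - v[seq(padlen + 1, 2)]
    post <- 2 * v[n] - v[seq(n - 1, n - padlen)]
    ext <- c(pre, v, post)
    zi <- sos_zi(filt$sos)
    y <- sosfilt_cpp(filt$sos, ext, zi * ext[1])
    y <- rev(y)
    y <- sosfilt_cpp(filt$sos, y, zi * y[1])
    rev(y)[padlen + seq_len(n)]
  })
}

apply_cols <- function(x, f) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- f(x[, j])
    out
  } else {
    f(x)
  }
}

#' Realized magnitude response of a designed filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| from the second-order sections for a
#' single (causal) pass. A zero-phase application via [sos_filtfilt()] has
#' magnitude `filter_gain(filt, f)^2`.
#'
#' @param filt a `butter_sos` object.
#' @param f frequency (vector) in Hz.
#' @return magnitude response at `f`.
#' @export
filter_gain <- function(filt, f) {
  vapply(f, function(fi) {
    z <- exp(-2i * pi * fi / filt$fs)
    h <- 1 + 0i
    for (s in seq_len(nrow(filt$sos))) {
      b <- filt$sos[s, 1:3]; a <- filt$sos[s, 4:6]
      h <- h * (b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2)
    }
    Mod(h)
  }, numeric(1))
}

#' Analytic Butterworth magnitude (analog closed form)
#'
#' The textbook magnitude of an order-`n` Butterworth filter, used as an
#' independent oracle for the realized digital designs (bilinear warping is
#' negligible at the package's band edges, which sit far below Nyquist).
#'
#' @param f frequency in Hz (vector).
#' @param cutoff cutoff in Hz (length 2 for `type = "pass"`).
#' @param order filter order.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return |H(f)| for a single pass.
#' @export
butter_gain_analytic <- function(f, cutoff, order, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (type == "low") {
    1 / sqrt(1 + (f / cutoff)^(2 * order))
  } else if (type == "high") {
    1 / sqrt(1 + (cutoff / f)^(2 * order))
  } else {
    fl <- cutoff[1]; fh <- cutoff[2]
    W <- (f^2 - fl * fh) / (f * (fh - fl))
    1 / sqrt(1 + W^(2 * order))
  }
}
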
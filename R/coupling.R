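#' Pearson coupling between ERP amplitudes and haemodynamic peaks
#'
#' Standard Pearson correlation between per-session electrophysiological
#' component amplitudes and per-session haemodynamic peak values, with the
#' two-sided p-value from the t transform on `n - 2` degrees of freedom and
#' the ordinary least-squares regression line.
#'
#' @param x,y equal-length numeric vectors (n >= 3, all finite); sessions
#'   (virtual participants) are the correlation unit.
#' @return object of class `coupling_result` with `r`, `p`, `n`, `slope`,
#'   `intercept`.
#' @export
pearson_coupling <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_fnirseeg("need equal-length vectors with n >= 3",
                   "invalid_parameter")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_fnirseeg("inputs must be finite", "invalid_parameter")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_fnirseeg("zero variance in an input vector", "degenerate_input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  slope <- stats::cov(x, y) / stats::var(x)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 slope = slope, intercept = mean(y) - slope * mean(x)),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> r = %.3f, p = %.4g, n = %d (y = %.3g + %.3g x)\n",
              x$r, x$p, x$n, x$intercept, x$slope))
  invisible(x)
}

#' Paired comparison of a component between two channels
#'
#' One-way repeated-measures ANOVA with two within-subject levels (e.g. the
#' same component at Fp1 and Fp2 across sessions), computed through its
#' exact paired-t equivalence: `F = t^2` with 1 and `n - 1` degrees of
#' freedom, identical two-sided p-value.
#'
#' @param a,b paired amplitude vectors (same sessions, two channels),
#'   n >= 3. Identical vectors give `F = 0`, `p = 1`; a constant non-zero
#'   shift (zero variance of the differences) is degenerate and raises an
#'   error.
#' @return list with `F`, `t`, `df`, `p`, `n`.
#' @export
paired_channel_comparison <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    abort_fnirseeg("need paired vectors with n >= 3", "invalid_parameter")
  }
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(F = 0, t = 0, df = c(1, n - 1), p = 1, n = n))
    }
    abort_fnirseeg("zero variance of the paired differences",
                   "degenerate_input")
  }
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  Fstat <- tstat^2
  p <- stats::pf(Fstat, 1, n - 1, lower.tail = FALSE)
  list(F = Fstat, t = tstat, df = c(1, n - 1), p = p, n = n)
}
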
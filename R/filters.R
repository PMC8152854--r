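# Filtering: zero-phase Bessel band-pass, mains notch, anti-aliased decimation.
#
# The analog Bessel low-pass prototype is designed here (reverse Bessel
# polynomial poles, numerically normalized so the -3 dB point sits at
# 1 rad/s); band transforms and discretization reuse signal::sftrans /
# signal::bilinear. Filters are applied forward-backward (signal::filtfilt)
# as a cascade of biquad sections, so high orders stay numerically stable
# and event onset times are not biased by group delay.

# reverse Bessel polynomial coefficients, ascending powers s^0..s^n
.bessel_poly <- function(n) {
  k <- 0:n
  exp(lgamma(2 * n - k + 1) - (n - k) * log(2) - lgamma(k + 1) - lgamma(n - k + 1))
}

# analog low-pass prototype: poles (gain = prod(-poles)) with -3 dB at 1 rad/s
.bessel_prototype <- function(n) {
  cf <- .bessel_poly(n)
  p <- polyroot(cf)                      # poles of a0 / theta_n(s), all LHP
  g <- Re(prod(-p))
  mag2 <- function(w) (Mod(g) / Mod(prod(1i * w - p)))^2
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(1e-3, 10 * n))$root
  p <- p / w3                            # frequency-normalize to -3 dB at 1 rad/s
  list(poles = p, gain = Re(prod(-p)))
}

# digital zero/pole/gain -> list of biquad (b, a) sections; gain on first section
.zpg_sos <- function(zero, pole, gain) {
  pair_up <- function(r) {
    out <- list(); used <- rep(FALSE, length(r))
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) > 1e-9) {
        j <- which(!used & abs(r - Conj(r[i])) < 1e-6)[1]
        if (is.na(j)) stop("unpaired complex root in filter design")
        used[j] <- TRUE
        out[[length(out) + 1L]] <- c(r[i], r[j])
      } else {
        j <- which(!used & abs(Im(r)) <= 1e-9)[1]
        if (is.na(j)) { out[[length(out) + 1L]] <- r[i] }
        else { used[j] <- TRUE; out[[length(out) + 1L]] <- c(r[i], r[j]) }
      }
    }
    out
  }
  zp <- pair_up(zero); pp <- pair_up(pole)
  ns <- max(length(zp), length(pp))
  sos <- vector("list", ns)
  for (s in seq_len(ns)) {
    b <- if (s <= length(zp)) Re(signal::poly(zp[[s]])) else 1
    a <- if (s <= length(pp)) Re(signal::poly(pp[[s]])) else 1
    sos[[s]] <- list(b = b, a = a)
  }
  sos[[1]]$b <- sos[[1]]$b * Re(gain)
  sos
}

# design a digital Bessel filter as biquad sections
# type: "low"/"high" with scalar w, "pass" with w = c(low, high); w in Hz
.bessel_design <- function(n, w, fs, type) {
  if (any(w <= 0) || any(w >= fs / 2))
    stop("filter corner(s) must lie in (0, fs/2)", call. = FALSE)
  proto <- .bessel_prototype(n)
  T <- 2
  warped <- 2 / T * tan(pi * w / fs)
  s <- signal::sftrans(numeric(0), proto$poles, proto$gain, W = warped,
                       stop = (type == "high"))
  if (type == "pass") {
    # sftrans with W = c(lo, hi) performs the low-pass -> band-pass transform
  }
  z <- signal::bilinear(s$zero, s$pole, s$gain, T)
  .zpg_sos(z$zero, z$pole, z$gain)
}

.apply_sos_filtfilt <- function(x, sos) {
  for (sec in sos) x <- signal::filtfilt(sec$b, sec$a, x)
  x
}

#' Zero-phase Bessel band-pass filter
#'
#' Band-pass filters a trace with an 8-pole Bessel characteristic, applied
#' forward-backward so the net phase response is zero (the effective
#' magnitude order doubles). Corner frequencies are pre-warped so the
#' \eqn{-3} dB points sit at the stated corners. The band-pass is realised
#' as a cascade of an 8-pole high-pass at `low` and an 8-pole low-pass at
#' `high`, each factored into biquad sections for numerical stability at
#' corners far below Nyquist (e.g. 2 Hz at 5000 Hz sampling).
#'
#' The defaults (2-200 Hz) are the band used to flatten DC-like shifts and
#' suppress high-frequency noise before measuring low-voltage-fast onset
#' amplitudes; slice field potentials use 0.2-500 Hz.
#'
#' @param x A `trace`.
#' @param low,high Band corners in Hz, `0 < low < high < fs/2`.
#' @param order Analog prototype order per section (default 8).
#' @return The filtered `trace`.
#' @export
bandpass_bessel <- function(x, low = 2, high = 200, order = 8) {
  stopifnot(inherits(x, "trace"))
  if (!(low > 0 && low < high && high < x$fs / 2))
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  hp <- .bessel_design(order, low, x$fs, "high")
  lp <- .bessel_design(order, high, x$fs, "low")
  y <- .apply_sos_filtfilt(x$samples, hp)
  y <- .apply_sos_filtfilt(y, lp)
  trace(y, x$fs, x$channel, x$units, x$t0)
}

#' Mains notch filter
#'
#' Zero-phase IIR notch removing a narrow band around `center` (default
#' 60 +/- 3 Hz, the power-line setting used during acquisition). A biquad
#' with unit-circle zeros at the notch frequency is applied
#' forward-backward; signals a half-width away are attenuated, while
#' components one octave below pass essentially unchanged.
#'
#' @param x A `trace`.
#' @param center Notch center frequency, Hz.
#' @param half_width Half-width of the notch, Hz.
#' @return The filtered `trace`.
#' @export
notch <- function(x, center = 60, half_width = 3) {
  stopifnot(inherits(x, "trace"))
  if (center >= x$fs / 2) stop("notch center must be below fs/2", call. = FALSE)
  w0 <- 2 * pi * center / x$fs
  q <- center / (2 * half_width)
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  trace(signal::filtfilt(b, a, x$samples), x$fs, x$channel, x$units, x$t0)
}

#' Downsample a trace with anti-alias filtering
#'
#' Decimates by an integer factor via [signal::decimate] (IIR anti-alias
#' low-pass applied zero-phase) or by a rational factor via
#' [signal::resample]. Warns when the new Nyquist frequency falls below
#' `amp_max_hz`, the top of the default amplitude band used for
#' phase-amplitude coupling, since coupling up to that frequency can no
#' longer be computed from the decimated trace.
#'
#' @param x A `trace`.
#' @param factor Decimation factor (>= 1; non-integer factors are resampled
#'   rationally).
#' @param amp_max_hz Highest analysis frequency the caller intends to use
#'   (default 512 Hz); set to `NA` to suppress the Nyquist warning.
#' @return The decimated `trace` with `fs = fs / factor`.
#' @export
downsample <- function(x, factor, amp_max_hz = 512) {
  stopifnot(inherits(x, "trace"))
  if (!is.numeric(factor) || factor < 1) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1) return(x)
  fs_new <- x$fs / factor
  if (!is.na(amp_max_hz) && fs_new / 2 < amp_max_hz)
    warning(sprintf(
      "downsampled Nyquist %.4g Hz is below the %.4g Hz analysis band",
      fs_new / 2, amp_max_hz), call. = FALSE)
  if (abs(factor - round(factor)) < 1e-9) {
    y <- signal::decimate(x$samples, round(factor), ftype = "iir")
  } else {
    # rational approximation p/q of the rate ratio fs_new/fs
    fr <- .rational(1 / factor)
    y <- signal::resample(x$samples, fr[1], fr[2])
  }
  trace(y, fs_new, x$channel, x$units, x$t0)
}

# continued-fraction rational approximation c(p, q) of r with q <= 1000
.rational <- function(r, max_den = 1000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    x <- 1 / (x - a)
  }
  c(as.integer(p1), as.integer(q1))
}
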
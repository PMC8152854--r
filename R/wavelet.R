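# Complex Morlet continuous wavelet transform.
#
# Mother wavelet (time domain): psi(t) = (pi*bw)^(-1/2) exp(-t^2/bw)
# exp(j 2 pi fc t) with fc = 0.8125 Hz and bw = 5 (Gaussian-envelope
# bandwidth parameter). Its Fourier transform is a unit-peak Gaussian
# centred at fc, so with L1-normalised daughters the transform has unit
# gain at each analysis frequency; coefficients are additionally scaled by
# 2 so |W(t, f0)| of a pure cosine of amplitude A at f0 equals A.
# The daughter at analysis frequency f is the mother dilated by a = fc/f
# (standard scale-frequency convention). The transform is computed by
# frequency-domain multiplication; the filter is one-sided (analytic), so
# phases and envelopes follow directly from the complex coefficients.

#' Morlet mother-wavelet parameters
#'
#' Defaults follow the parameterization used for human EEG coupling work:
#' central frequency 0.8125 Hz and bandwidth parameter 5. For this pair the
#' effective quality factor fc / sigma_f is about 8, i.e. each daughter
#' wavelet resolves roughly an eighth-octave band around its analysis
#' frequency.
#'
#' @param center_frequency Mother-wavelet central frequency, Hz.
#' @param bandwidth Gaussian-envelope bandwidth parameter (s^2 scale).
#' @return A `morlet_params` list.
#' @export
morlet_params <- function(center_frequency = 0.8125, bandwidth = 5) {
  stopifnot(center_frequency > 0, bandwidth > 0)
  structure(list(center_frequency = center_frequency, bandwidth = bandwidth),
            class = "morlet_params")
}

#' Logarithmically spaced frequency grid
#'
#' Geometric frequency sequence from `fmin` to `fmax` inclusive, with a
#' constant ratio between consecutive entries chosen as close as possible
#' to `points_per_octave` points per octave while hitting both endpoints
#' exactly. This is the grid type used for the coupling comodulogram axes
#' (1-30 Hz phase, 32-512 Hz amplitude) and the coherence axis
#' (0.25-512 Hz).
#'
#' @param fmin,fmax Grid bounds, Hz, `0 < fmin < fmax`.
#' @param points_per_octave Grid density (default 4).
#' @return Numeric vector of frequencies, class `freq_grid`.
#' @export
make_log_grid <- function(fmin, fmax, points_per_octave = 4) {
  if (!(fmin > 0 && fmax > fmin)) stop("need 0 < fmin < fmax", call. = FALSE)
  n_int <- max(1L, round(points_per_octave * log2(fmax / fmin)))
  f <- fmin * (fmax / fmin)^(seq(0, n_int) / n_int)
  f[length(f)] <- fmax
  structure(f, class = c("freq_grid", "numeric"))
}

# frequency response of the L1-normalised analytic daughter at frequency f,
# evaluated at angular frequencies omega (rad/s); unit peak at 2*pi*f
.morlet_response <- function(omega, f, params) {
  a <- params$center_frequency / f
  h <- exp(-params$bandwidth * (a * omega - 2 * pi * params$center_frequency)^2 / 4)
  h[omega < 0] <- 0
  h
}

# envelope e-folding time (s) of the daughter at frequency f
.morlet_efold <- function(f, params) {
  params$center_frequency * sqrt(params$bandwidth) / f
}

#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' Computes complex wavelet coefficients of a trace on a frequency grid via
#' frequency-domain convolution with analytic Morlet daughters. The
#' transform is linear and amplitude-calibrated: a pure cosine of amplitude
#' A at a grid frequency yields |W| = A along that row (away from edges).
#'
#' @param x A `trace`.
#' @param grid Frequencies in Hz ([make_log_grid()] or any increasing
#'   vector), all below `fs/2`.
#' @param params [morlet_params()].
#' @return A `wavelet_spectrum`: list with `coefficients` (complex matrix,
#'   n_samples x n_frequencies), `grid`, `fs`, `t0`, and `coi_s` (per
#'   frequency, the edge span in seconds inside which coefficients are
#'   boundary-contaminated: one envelope e-folding time).
#' @export
cwt_morlet <- function(x, grid, params = morlet_params()) {
  stopifnot(inherits(x, "trace"))
  grid <- as.numeric(grid)
  if (any(grid <= 0) || any(grid >= x$fs / 2))
    stop("grid frequencies must lie in (0, fs/2)", call. = FALSE)
  n <- length(x$samples)
  pad <- ceiling(3 * .morlet_efold(min(grid), params) * x$fs)
  nfft <- stats::nextn(n + pad, c(2, 3, 5))
  X <- stats::fft(c(x$samples, rep(0, nfft - n)))
  k <- c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1):1))
  omega <- 2 * pi * k * x$fs / nfft
  W <- matrix(0i, n, length(grid))
  for (j in seq_along(grid)) {
    H <- 2 * .morlet_response(omega, grid[j], params)
    W[, j] <- (stats::fft(X * H, inverse = TRUE) / nfft)[seq_len(n)]
  }
  structure(list(coefficients = W, grid = grid, fs = x$fs, t0 = x$t0,
                 coi_s = .morlet_efold(grid, params)),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d samples x %d frequencies (%.3g-%.3g Hz), fs=%g Hz\n",
              nrow(x$coefficients), length(x$grid), min(x$grid), max(x$grid), x$fs))
  invisible(x)
}

#' Instantaneous phase of a wavelet spectrum
#'
#' Four-quadrant angle of each complex coefficient, in (-pi, pi]. (The
#' quotient form Im/Re passed through a plain arctangent loses the
#' quadrant; the four-quadrant angle is the faithful reading.)
#'
#' @param spectrum A `wavelet_spectrum`.
#' @return Matrix of phases (radians), same shape as the coefficients.
#' @export
extract_phase <- function(spectrum) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  Arg(spectrum$coefficients)
}

#' Instantaneous amplitude of a wavelet spectrum
#'
#' Complex modulus `|Re + j Im|` of each coefficient.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @return Nonnegative matrix, same shape as the coefficients.
#' @export
extract_amplitude <- function(spectrum) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  Mod(spectrum$coefficients)
}

#' Cone-of-influence mask
#'
#' @param spectrum A `wavelet_spectrum`.
#' @return Logical matrix, `TRUE` where the coefficient lies within one
#'   envelope e-folding time of either trace edge (boundary-contaminated).
#' @export
coi_mask <- function(spectrum) {
  n <- nrow(spectrum$coefficients)
  t_rel <- (seq_len(n) - 1) / spectrum$fs
  outer(t_rel, spectrum$coi_s, "<") |
    outer(max(t_rel) - t_rel, spectrum$coi_s, "<")
}
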
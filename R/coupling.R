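# Phase-amplitude coupling (Kullback-Leibler modulation index over
# 20-degree phase bins, comodulograms on log-spaced grids, 4-s sliding
# windows, peri-ictal averaging) and wavelet phase coherence between
# paired recording sites.

#' Kullback-Leibler modulation index
#'
#' Tort-style coupling strength: phases are binned into `n_bins` equal bins
#' over (-pi, pi] (18 bins of 20 degrees by default), the mean amplitude
#' per bin is normalized into a distribution p, and the MI is the
#' Kullback-Leibler divergence of p from the uniform distribution divided
#' by `log(n_bins)`. MI is 0 when the amplitude is uniform over phase and 1
#' when all amplitude mass concentrates in a single bin.
#'
#' Empty bins contribute zero to the divergence (`0 * log 0 = 0`). An
#' all-zero amplitude series has no amplitude distribution: the MI is
#' undefined and `NA` is returned with a warning.
#'
#' @param phase Phases in radians (any values; wrapped into (-pi, pi]).
#' @param amplitude Nonnegative amplitudes, same length as `phase`.
#' @param n_bins Number of phase bins (default 18, i.e. 20-degree bins).
#' @return A single MI value in \[0, 1\] (or `NA`).
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude))
    stop("phase and amplitude must have equal length", call. = FALSE)
  if (any(amplitude < 0)) stop("amplitudes must be nonnegative", call. = FALSE)
  tot <- sum(amplitude)
  if (tot == 0) {
    warning("all-zero amplitude: modulation index undefined", call. = FALSE)
    return(NA_real_)
  }
  # wrap into (-pi, pi], then bin
  ph <- phase - 2 * pi * ceiling((phase - pi) / (2 * pi))
  k <- pmin(n_bins, pmax(1L, ceiling((ph + pi) / (2 * pi / n_bins))))
  msum <- rowsum(amplitude, k)
  cnt <- tabulate(k, n_bins)
  p <- numeric(n_bins)
  p[as.integer(rownames(msum))] <- msum[, 1] / pmax(cnt[as.integer(rownames(msum))], 1L)
  p <- p / sum(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] * n_bins)) / log(n_bins)
}

# MI for a matrix of amplitudes (columns share one phase series); returns a
# vector of MI values, one per column
.mi_cols <- function(k, amp, n_bins) {
  cnt <- tabulate(k, n_bins)
  sums <- rowsum(amp, k)
  p <- matrix(0, n_bins, ncol(amp))
  rows <- as.integer(rownames(sums))
  p[rows, ] <- sums / pmax(cnt[rows], 1L)
  cs <- colSums(p)
  bad <- cs == 0
  cs[bad] <- 1
  p <- sweep(p, 2, cs, "/")
  lp <- p * log(p * n_bins)
  lp[p == 0] <- 0
  mi <- colSums(lp) / log(n_bins)
  mi[bad] <- NA_real_
  mi
}

#' Windowed phase-amplitude comodulograms
#'
#' Computes the Morlet wavelet transform of the trace on the phase grid
#' (1-30 Hz by default) and amplitude grid (32-512 Hz), then for each
#' consecutive non-overlapping window of `window_s` seconds (4 s, long
#' enough for at least 4 cycles of every phase frequency at or above 1 Hz)
#' computes the modulation index for every (phase frequency, amplitude
#' frequency) pair. Windows containing large movement artifacts (samples
#' beyond `artifact_threshold_sd` robust SDs) are flagged excluded; phase
#' rows with fewer than `min_cycles` cycles per window are flagged
#' unreliable.
#'
#' @param x A `trace`; `fs/2` must exceed the top of the amplitude grid.
#' @param phase_grid,amp_grid Frequency grids in Hz ([make_log_grid()]).
#' @param window_s Window length in seconds (default 4).
#' @param params [morlet_params()].
#' @param artifact_threshold_sd Artifact threshold in robust SDs (default
#'   8); `Inf` disables masking.
#' @param min_cycles Minimum cycles per window for a reliable phase row.
#' @return A `pac_windows` object: list with `starts` (window start times),
#'   `window_s`, `mi` (array n_windows x n_phase x n_amp), `phase_grid`,
#'   `amp_grid`, `excluded` (logical per window), `reliable_phase`
#'   (logical per phase frequency).
#' @export
pac_windows <- function(x, phase_grid = make_log_grid(1, 30),
                        amp_grid = make_log_grid(32, 512), window_s = 4,
                        params = morlet_params(),
                        artifact_threshold_sd = 8, min_cycles = 4) {
  stopifnot(inherits(x, "trace"))
  if (max(amp_grid) >= x$fs / 2)
    stop("amplitude grid exceeds Nyquist; downsample less or reduce the grid",
         call. = FALSE)
  n_win <- floor(duration(x) / window_s)
  if (n_win < 1) stop("trace shorter than one window", call. = FALSE)
  spec <- cwt_morlet(x, c(as.numeric(phase_grid), as.numeric(amp_grid)), params)
  npf <- length(phase_grid)
  ph <- Arg(spec$coefficients[, seq_len(npf), drop = FALSE])
  am <- Mod(spec$coefficients[, npf + seq_along(amp_grid), drop = FALSE])
  wlen <- round(window_s * x$fs)
  excluded <- artifact_mask(x, n_win, window_s, artifact_threshold_sd)
  mi <- array(NA_real_, c(n_win, npf, length(amp_grid)))
  nb <- 18L
  for (w in seq_len(n_win)) {
    i <- ((w - 1) * wlen + 1):(w * wlen)
    for (j in seq_len(npf)) {
      pj <- ph[i, j]
      k <- pmin(nb, pmax(1L, ceiling((pj + pi) / (2 * pi / nb))))
      mi[w, j, ] <- .mi_cols(k, am[i, , drop = FALSE], nb)
    }
  }
  structure(list(starts = x$t0 + (seq_len(n_win) - 1) * window_s,
                 window_s = window_s, mi = mi,
                 phase_grid = as.numeric(phase_grid),
                 amp_grid = as.numeric(amp_grid),
                 excluded = excluded,
                 reliable_phase = as.numeric(phase_grid) * window_s >= min_cycles),
            class = "pac_windows")
}

#' @export
print.pac_windows <- function(x, ...) {
  cat(sprintf("<pac_windows> %d windows of %g s, %d x %d grid, %d excluded\n",
              length(x$starts), x$window_s, length(x$phase_grid),
              length(x$amp_grid), sum(x$excluded)))
  invisible(x)
}

#' Window-averaged comodulogram
#'
#' Mean MI matrix over non-excluded windows.
#'
#' @param pw A `pac_windows` object.
#' @return Matrix (n_phase x n_amp) of mean MI.
#' @export
comodulogram <- function(pw) {
  stopifnot(inherits(pw, "pac_windows"))
  keep <- !pw$excluded
  if (!any(keep)) stop("all windows excluded", call. = FALSE)
  apply(pw$mi[keep, , , drop = FALSE], c(2, 3), mean)
}

#' Mean PAC per peri-ictal segment
#'
#' Spectral and temporal averaging of the coupling strength: for each
#' peri-ictal segment, every non-excluded window whose centre falls inside
#' the segment contributes the mean of its comodulogram over the full
#' (reliable) phase x amplitude grid, and those window means are averaged.
#' A segment whose windows are all excluded (or that holds no window) is
#' reported missing.
#'
#' @param pw A `pac_windows` object.
#' @param segmentation Output of [segment_epochs()].
#' @return A `data.frame`: `segment`, `mean_mi`, `n_windows`.
#' @export
mean_pac <- function(pw, segmentation) {
  stopifnot(inherits(pw, "pac_windows"))
  ctr <- pw$starts + pw$window_s / 2
  rel <- pw$reliable_phase
  if (!any(rel)) stop("no reliable phase rows", call. = FALSE)
  wmean <- apply(pw$mi[, rel, , drop = FALSE], 1, mean)
  out <- lapply(seq_len(nrow(segmentation)), function(i) {
    sel <- ctr >= segmentation$start_s[i] & ctr < segmentation$end_s[i] &
      !pw$excluded
    data.frame(segment = segmentation$segment[i],
               mean_mi = if (any(sel)) mean(wmean[sel]) else NA_real_,
               n_windows = sum(sel))
  })
  do.call(rbind, out)
}

#' Movement-artifact window mask
#'
#' Flags analysis windows containing large transients: a window is masked
#' when any sample deviates from the trace median by more than
#' `threshold_sd` robust SDs.
#'
#' @param x A `trace`.
#' @param n_win Number of consecutive windows.
#' @param window_s Window length, seconds.
#' @param threshold_sd Threshold in robust (MAD-based) SDs; `Inf` masks
#'   nothing.
#' @return Logical vector of length `n_win`; `TRUE` = masked.
#' @export
artifact_mask <- function(x, n_win, window_s = 4, threshold_sd = 8) {
  stopifnot(inherits(x, "trace"))
  if (!is.finite(threshold_sd)) return(rep(FALSE, n_win))
  med <- stats::median(x$samples)
  rsd <- stats::mad(x$samples)
  wlen <- round(window_s * x$fs)
  vapply(seq_len(n_win), function(w) {
    i <- ((w - 1) * wlen + 1):min(w * wlen, length(x$samples))
    any(abs(x$samples[i] - med) > threshold_sd * rsd)
  }, logical(1))
}

#' Wavelet phase coherence between two traces
#'
#' For each grid frequency f, the instantaneous phase difference is taken
#' as the angle of the wavelet cross-spectrum,
#' `dphi(t) = Arg(Conj(W1) * W2)`, and coherence within each consecutive
#' window of `cycles / f` seconds is the modulus of the window-mean unit
#' phasor `|mean(exp(1i dphi))|`, a value in \[0, 1\] that reaches 1
#' exactly when the phase difference is constant over the window (a phase
#' lock). The map is tiled per frequency (window length is
#' frequency-dependent), so results are stored per frequency as window
#' centres and coherence values; [wpc_matrix()] resamples onto a common
#' time axis for display.
#'
#' @param a,b Two `trace` objects with equal `fs`, `t0` and length.
#' @param grid Frequencies in Hz (default 0.25-512 Hz log grid, capped
#'   below Nyquist).
#' @param cycles Window length in cycles of each frequency (default 8).
#' @param params [morlet_params()].
#' @return A `coherence_map`: list with `freqs`, and per frequency
#'   `centers` (s), `rho` (within-window coherence) and `dphi` (the
#'   window's net phase difference, radians).
#' @export
wpc <- function(a, b, grid = NULL, cycles = 8, params = morlet_params()) {
  stopifnot(inherits(a, "trace"), inherits(b, "trace"))
  if (a$fs != b$fs || length(a$samples) != length(b$samples) ||
      abs(a$t0 - b$t0) > 1e-9)
    stop("traces must share sampling rate, length and time base", call. = FALSE)
  if (is.null(grid))
    grid <- make_log_grid(0.25, min(512, 0.45 * a$fs))
  grid <- as.numeric(grid)
  Wa <- cwt_morlet(a, grid, params)$coefficients
  Wb <- cwt_morlet(b, grid, params)$coefficients
  n <- nrow(Wa)
  res <- lapply(seq_along(grid), function(j) {
    f <- grid[j]
    wlen <- max(2L, round(cycles / f * a$fs))
    n_win <- floor(n / wlen)
    if (n_win < 1) return(list(centers = numeric(0), rho = numeric(0),
                               dphi = numeric(0)))
    cross <- Conj(Wa[, j]) * Wb[, j]
    u <- exp(1i * Arg(cross))
    centers <- a$t0 + ((seq_len(n_win) - 0.5) * wlen) / a$fs
    rho <- numeric(n_win); dphi <- numeric(n_win)
    for (w in seq_len(n_win)) {
      i <- ((w - 1) * wlen + 1):(w * wlen)
      rho[w] <- Mod(mean(u[i]))
      dphi[w] <- Arg(sum(cross[i]))
    }
    list(centers = centers, rho = rho, dphi = dphi)
  })
  structure(list(freqs = grid, windows = res, fs = a$fs,
                 channels = c(a$channel, b$channel), cycles = cycles),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf("<coherence_map> %s vs %s, %d frequencies (%.3g-%.3g Hz), %d cycles/window\n",
              x$channels[1], x$channels[2], length(x$freqs), min(x$freqs),
              max(x$freqs), x$cycles))
  invisible(x)
}

#' Coherence map on a common time axis
#'
#' Nearest-neighbour resampling of the per-frequency window values onto a
#' shared time axis (for display or joint summaries).
#'
#' @param map A `coherence_map`.
#' @param times Target time axis in seconds; defaults to 1-s steps over the
#'   map extent.
#' @return Matrix (length(times) x n_frequencies) of coherence values.
#' @export
wpc_matrix <- function(map, times = NULL) {
  stopifnot(inherits(map, "coherence_map"))
  if (is.null(times)) {
    rng <- range(unlist(lapply(map$windows, `[[`, "centers")))
    times <- seq(rng[1], rng[2], by = 1)
  }
  out <- matrix(NA_real_, length(times), length(map$freqs))
  for (j in seq_along(map$freqs)) {
    w <- map$windows[[j]]
    if (!length(w$centers)) next
    idx <- vapply(times, function(t) which.min(abs(w$centers - t)), integer(1))
    out[, j] <- w$rho[idx]
  }
  dimnames(out) <- list(NULL, signif(map$freqs, 4))
  out
}

#' Across-window coherence summary
#'
#' Collapses a coherence map over time: per frequency, each window
#' contributes one unit phasor at its net phase difference, and the
#' modulus of their mean is returned together with the window count. For a
#' phase-locked pair this equals 1 at the locked frequency; for independent
#' inputs the window phasors are approximately independent and uniform, so
#' the expected value is the small-sample resultant bias
#' `sqrt(pi / (4 n))` for `n` windows ([wpc_null_level()]).
#'
#' @param map A `coherence_map`.
#' @return A `data.frame`: `freq_hz`, `rho`, `n_windows`.
#' @export
wpc_collapse <- function(map) {
  stopifnot(inherits(map, "coherence_map"))
  out <- lapply(seq_along(map$freqs), function(j) {
    w <- map$windows[[j]]
    data.frame(freq_hz = map$freqs[j],
               rho = if (length(w$dphi)) Mod(mean(exp(1i * w$dphi))) else NA_real_,
               n_windows = length(w$dphi))
  })
  do.call(rbind, out)
}

#' Expected coherence of independent signals
#'
#' Small-sample bias of the resultant length: the mean modulus of the
#' average of `n` independent unit phasors with uniform phases,
#' `sqrt(pi / (4 n))` to leading order.
#'
#' @param n Number of independent windows.
#' @return Expected null coherence.
#' @export
wpc_null_level <- function(n) sqrt(pi / (4 * n))
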
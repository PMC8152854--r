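# Event detection and classification.
#
# In vivo: spontaneous electrographic discharges are recognised as
# repetitive spikes with amplitudes about twice the background and
# durations of at least 10 s; onsets are classified as low-voltage fast
# (LVF: abrupt attenuation of background to <= 65% of the preceding signal
# for 0.5-5 s before rhythmic spiking), hypersynchronous (HYP: a cluster of
# abruptly arising large spikes), or incremental (spikes ramping up from
# baseline). In vitro: sharp waves (about 2x background, 20-200 ms base,
# 0.3-4 events/s), interictal spikes (>= 0.5 mV, 200-600 ms, 2-5 events per
# 10 s) and ictal discharges (>= 1 mV peaks, mean duration >= 30 s, mean
# inter-event interval >= 90 s).

#' Discharge-detector parameters
#'
#' @param background_window_s One-sided span of the trailing window over
#'   which the rolling background level is estimated (default 30 s; the
#'   estimator uses twice this span).
#' @param amplitude_factor Spike threshold in background-SD multiples
#'   (default 2, the recognition rule).
#' @param min_duration_s Minimum discharge duration (default 10 s).
#' @param spike_gap_tolerance_s Spikes separated by less than this gap
#'   belong to one event (default 2 s).
#' @param suppression_check_s Post-termination window checked for signal
#'   suppression (default 2 s).
#' @param suppression_factor Envelope must stay below this multiple of
#'   background during the suppression check (default 1.5).
#' @param lvf_max_pct LVF attenuation criterion, percent of preceding
#'   signal (default 65).
#' @param lvf_search_s How far before the first spike the attenuation scan
#'   extends (default 6 s, covering the 0.5-5 s LVF length range).
#' @param min_spikes Minimum number of suprathreshold spikes for an event.
#' @return A `detection_params` list.
#' @export
detection_params <- function(background_window_s = 30, amplitude_factor = 2,
                             min_duration_s = 10, spike_gap_tolerance_s = 2,
                             suppression_check_s = 2, suppression_factor = 1.5,
                             lvf_max_pct = 65, lvf_search_s = 6,
                             min_spikes = 5) {
  vals <- c(background_window_s, amplitude_factor, min_duration_s,
            spike_gap_tolerance_s, suppression_check_s, suppression_factor,
            lvf_max_pct, lvf_search_s, min_spikes)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all detection parameters must be positive", call. = FALSE)
  structure(as.list(environment()), class = "detection_params")
}

# per-1-s-block statistic of the signal
.block_stat <- function(x, fs, stat, block_s = 1) {
  nb <- max(1L, floor(length(x) / (block_s * fs)))
  vapply(seq_len(nb), function(b) {
    i0 <- round((b - 1) * block_s * fs) + 1L
    i1 <- min(length(x), round(b * block_s * fs))
    stat(x[i0:i1])
  }, numeric(1))
}

# "background signal" amplitude: the typical envelope peak of the
# background (95th percentile of |x| per 1-s block), tracked as the
# trailing 0.2-quantile of block values so that discharges occupying up to
# ~3/4 of the trailing window do not inflate it. The discharge amplitude
# rule ("about 2x the background signals") thresholds spike peaks against
# this amplitude, not against the background SD: a Gaussian background
# exceeds 2 SD routinely, but rarely 2x its own envelope peaks.
.rolling_bg_amp <- function(x, fs, window_s) {
  bs <- .block_stat(x, fs, function(v) stats::quantile(abs(v), 0.95, names = FALSE))
  w <- max(5L, round(2 * window_s))
  bg <- vapply(seq_along(bs), function(b) {
    stats::quantile(bs[max(1L, b - w):b], 0.2, names = FALSE)
  }, numeric(1))
  function(t) bg[pmin(length(bg), pmax(1L, ceiling(pmax(t, 1e-9))))]
}

# suprathreshold spike peaks of |x| (threshold may vary per sample):
# data.frame(time, amp), peaks closer than 120 ms (one biphasic waveform)
# collapsed onto the largest
.spike_peaks <- function(x, fs, thr) {
  none <- data.frame(time = numeric(0), amp = numeric(0),
                     t_on = numeric(0), t_off = numeric(0))
  supra <- abs(x) > thr
  supra[is.na(supra)] <- FALSE
  if (!any(supra)) return(none)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  runs <- cbind(starts[keep], ends[keep])
  pk <- vapply(seq_len(nrow(runs)), function(k) {
    i <- runs[k, 1]:runs[k, 2]
    i[which.max(abs(x[i]))]
  }, integer(1))
  grp <- cumsum(c(1, diff(pk) > 0.12 * fs))
  out <- lapply(unique(grp), function(g) {
    sel <- which(grp == g)
    i <- pk[sel][which.max(abs(x[pk[sel]]))]
    data.frame(time = (i - 1) / fs, amp = abs(x[i]),
               t_on = (min(runs[sel, 1]) - 1) / fs,
               t_off = max(runs[sel, 2]) / fs)
  })
  do.call(rbind, out)
}

# scan for an LVF attenuation window ending at the first spike: sliding
# 0.4-s windows must drop to <= lvf_max_pct of the preceding-signal SD for
# at least two consecutive windows reaching the first spike.
# Returns list(found, lvf_start, lvf_length, sd_ratio) in trace time.
.lvf_scan <- function(bp, fs, t0, first_spike, params) {
  win <- 0.4; step <- 0.1
  scan_from <- max(t0, first_spike - params$lvf_search_s)
  base_to <- scan_from
  base_from <- max(t0, base_to - 8)
  if (base_to - base_from < 1 || first_spike - scan_from < win)
    return(list(found = FALSE))
  seg <- function(a, b) bp[(round((a - t0) * fs) + 1L):min(length(bp), round((b - t0) * fs))]
  sd_base <- stats::sd(seg(base_from, base_to))
  starts <- seq(scan_from, first_spike - win, by = step)
  if (length(starts) < 2) return(list(found = FALSE))
  ratio <- vapply(starts, function(s) stats::sd(seg(s, s + win)) / sd_base,
                  numeric(1))
  low <- ratio <= params$lvf_max_pct / 100
  if (!any(low)) return(list(found = FALSE))
  # contiguous low run (>= 2 windows) reaching within 0.5 s of the first
  # spike (the criterion holds "in most cases": local SD wander can push
  # the last fraction of a genuine LVF window slightly above the line)
  r <- rle(low)
  ends <- cumsum(r$lengths); starts_i <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= 2 &
                  starts[pmin(ends, length(starts))] + win >=
                  first_spike - 5 * step)
  if (!length(cand)) return(list(found = FALSE))
  k <- cand[length(cand)]
  lvf_start <- starts[starts_i[k]]
  lvf_len <- first_spike - lvf_start
  if (lvf_len < 0.4 || lvf_len > 5.5) return(list(found = FALSE))
  list(found = TRUE, lvf_start = lvf_start, lvf_length = lvf_len,
       sd_ratio = mean(ratio[starts_i[k]:ends[k]]))
}

# trim stray crossings off the edges of a spike group: an edge spike of a
# "repetitive spike" train must either carry a typical spike amplitude
# (>= 60% of the group's median peak) or have company (another spike within
# 1.5 s); barely-suprathreshold isolated crossings of the background fail
# both.
.trim_group <- function(sp, min_spikes) {
  repeat {
    n <- nrow(sp)
    if (n < min_spikes) break
    med <- stats::median(sp$amp)
    drop_head <- sp$amp[1] < 0.6 * med && sp$time[2] - sp$time[1] > 0.4
    drop_tail <- sp$amp[n] < 0.6 * med && sp$time[n] - sp$time[n - 1] > 0.4
    if (!drop_head && !drop_tail) break
    if (drop_head) sp <- sp[-1, , drop = FALSE]
    if (drop_tail && nrow(sp)) sp <- sp[-nrow(sp), , drop = FALSE]
  }
  sp
}

# HYP / INCREMENTAL / UNCLASSIFIED from the spike amplitude profile
# (LVF is ruled out by the caller before this runs)
.classify_burst_shape <- function(bp, fs, w_t0, bg_amp, first_spike, term,
                                  params) {
  sp <- .spike_peaks(bp, fs, rep(params$amplitude_factor * bg_amp, length(bp)))
  sp$time <- sp$time + w_t0
  sp <- sp[sp$time >= first_spike - 0.2 & sp$time <= term, , drop = FALSE]
  if (nrow(sp) < 3) return("UNCLASSIFIED")
  e_sel <- sp$time <= first_spike + 1
  early <- sp$amp[e_sel]
  # a dense cluster can merge into one long suprathreshold run; count the
  # spikes it represents by its duration (one spike per ~0.3 s of run)
  n_early_eff <- sum(pmax(1, round((sp$t_off[e_sel] - sp$t_on[e_sel]) / 0.3)))
  plateau_sel <- sp$time > first_spike + 4 & sp$time <= first_spike + 12
  plateau <- if (any(plateau_sel)) stats::median(sp$amp[plateau_sel])
             else stats::median(sp$amp)
  if (length(early) >= 2 && stats::median(early) < 0.55 * plateau)
    return("INCREMENTAL")
  if (n_early_eff >= 3 && length(early) >= 1 &&
      stats::median(early) >= 0.6 * plateau &&
      stats::median(early) >= params$amplitude_factor * bg_amp)
    return("HYP")
  "UNCLASSIFIED"
}

#' Detect electrographic discharges
#'
#' Band-pass filters the trace to 2-200 Hz, estimates a rolling robust
#' background SD, finds suprathreshold spike peaks
#' (`|x| > amplitude_factor * background`), groups them into events
#' (gaps below `spike_gap_tolerance_s` merge), drops events shorter than
#' `min_duration_s` or with fewer than `min_spikes` spikes, extends each
#' onset backwards through an LVF attenuation window when one is present
#' (discharge duration runs from the LVF onset to spike cessation), and
#' checks for post-termination suppression. Onsets are classified with
#' [classify_onset()] unless `classify = FALSE`.
#'
#' @param x A `trace`.
#' @param params A [detection_params()].
#' @param classify Run onset classification on each event (default TRUE).
#' @return A `data.frame` (one row per event, sorted, non-overlapping):
#'   `event_id, channel, onset_s, termination_s, duration_s, onset_class,
#'   first_spike_s, n_spikes, suppressed, lvf_norm_sd_pct`.
#' @export
detect_discharges <- function(x, params = detection_params(), classify = TRUE) {
  stopifnot(inherits(x, "trace"), inherits(params, "detection_params"))
  if (anyNA(x$samples)) stop("trace contains NA samples", call. = FALSE)
  if (duration(x) <= params$background_window_s)
    stop("trace must be longer than background_window_s", call. = FALSE)
  empty <- data.frame(event_id = integer(), channel = character(),
                      onset_s = numeric(), termination_s = numeric(),
                      duration_s = numeric(), onset_class = character(),
                      first_spike_s = numeric(), n_spikes = integer(),
                      suppressed = logical(), lvf_norm_sd_pct = numeric())
  high <- min(200, 0.45 * x$fs)
  bp <- bandpass_bessel(x, 2, high)
  if (stats::sd(bp$samples) == 0) return(empty)
  bgf <- .rolling_bg_amp(bp$samples, x$fs, params$background_window_s)
  thr <- params$amplitude_factor * bgf((seq_along(bp$samples) - 0.5) / x$fs)
  pk <- .spike_peaks(bp$samples, x$fs, thr)
  pk[c("time", "t_on", "t_off")] <- pk[c("time", "t_on", "t_off")] + x$t0
  if (!nrow(pk)) return(empty)

  grp <- cumsum(c(1, diff(pk$time) > params$spike_gap_tolerance_s))
  rows <- list()
  for (g in unique(grp)) {
    sp <- .trim_group(pk[grp == g, , drop = FALSE], params$min_spikes)
    tg <- sp$time
    if (length(tg) < params$min_spikes) next
    first_spike <- sp$t_on[1]; last_spike <- sp$t_off[nrow(sp)]
    onset <- first_spike
    lvf <- .lvf_scan(bp$samples, x$fs, x$t0, first_spike, params)
    if (lvf$found) onset <- lvf$lvf_start
    term <- last_spike + 0.1
    dur <- term - onset
    if (dur < params$min_duration_s) next
    # suppression: envelope stays low after termination
    s0 <- .t2i(x, term + 0.2); s1 <- .t2i(x, term + 0.2 + params$suppression_check_s)
    post_sd <- if (s1 > s0)
      stats::quantile(abs(bp$samples[s0:s1]), 0.95, names = FALSE) else NA_real_
    bg_here <- bgf(first_spike - x$t0)
    cls <- if (!classify) "UNCLASSIFIED"
    else if (lvf$found) "LVF"
    else .classify_burst_shape(bp$samples, x$fs, x$t0, bg_here, first_spike,
                               term, params)
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = length(rows) + 1L, channel = x$channel,
      onset_s = onset, termination_s = term, duration_s = dur,
      onset_class = cls,
      first_spike_s = first_spike, n_spikes = length(tg),
      suppressed = isTRUE(post_sd < params$suppression_factor * bg_here),
      lvf_norm_sd_pct = if (lvf$found) 100 * lvf$sd_ratio else NA_real_)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_s), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  out
}

#' Classify a discharge onset
#'
#' Applies the onset taxonomy to one detected event:
#' * `LVF` if a 0.5-5 s window immediately before the first spikes has
#'   normalized SD at or below `lvf_max_pct` of the preceding signal;
#' * `HYP` if (with no attenuated window) the first second holds at least
#'   3 spikes at `>= amplitude_factor` background SDs whose size is already
#'   close to the event's plateau amplitude (an abrupt cluster);
#' * `INCREMENTAL` if early spikes are small relative to the plateau
#'   (amplitude ramping up from baseline);
#' * `UNCLASSIFIED` otherwise.
#'
#' @param x The `trace` the event was detected on.
#' @param event One row of the [detect_discharges()] output (or a list with
#'   `onset_s`, `termination_s`, optionally `first_spike_s`).
#' @param params A [detection_params()].
#' @return One of `"LVF"`, `"HYP"`, `"INCREMENTAL"`, `"UNCLASSIFIED"`.
#' @export
classify_onset <- function(x, event, params = detection_params()) {
  stopifnot(inherits(x, "trace"))
  onset <- event$onset_s; term <- event$termination_s
  if (is.null(onset) || onset < x$t0 || term > x$t0 + duration(x) + 1e-9)
    stop("event must lie within the trace", call. = FALSE)
  first_spike <- if (!is.null(event$first_spike_s) && is.finite(event$first_spike_s))
    event$first_spike_s else onset
  a <- max(x$t0, onset - 12)
  b <- min(x$t0 + duration(x), term)
  w <- trace_window(x, a, b)
  high <- min(200, 0.45 * x$fs)
  bp <- bandpass_bessel(w, 2, high)
  pre <- bp$samples[seq_len(max(10, round((first_spike - a - 0.5) * x$fs)))]
  bg <- stats::quantile(abs(pre), 0.95, names = FALSE)
  lvf <- .lvf_scan(bp$samples, x$fs, w$t0, first_spike, params)
  if (lvf$found) return("LVF")
  .classify_burst_shape(bp$samples, x$fs, w$t0, bg, first_spike, term, params)
}

#' Quantify a low-voltage fast onset
#'
#' Filters the trace to 2-200 Hz (flattening DC-like shifts and
#' high-frequency noise), then computes the SD of the LVF window and of the
#' equal-length window immediately preceding it; the LVF SD is expressed as
#' a percentage of the preceding SD.
#'
#' @param x A `trace`.
#' @param event A detected event row (used only for validation; may be
#'   `NULL`).
#' @param lvf_window `c(start_s, length_s)` of the LVF window; length must
#'   be at least 0.5 s.
#' @return An `lvf_metrics` list: `lvf_start_s`, `lvf_length_s`, `sd_lvf`,
#'   `sd_preceding`, `normalized_sd_pct`.
#' @export
quantify_lvf <- function(x, event = NULL, lvf_window) {
  stopifnot(inherits(x, "trace"), length(lvf_window) == 2)
  start <- lvf_window[1]; len <- lvf_window[2]
  if (len < 0.5) stop("LVF window must be at least 0.5 s", call. = FALSE)
  if (start - len < x$t0)
    stop("no equal-length preceding window available", call. = FALSE)
  if (!is.null(event) &&
      (start < event$onset_s - 1e-6 || start + len > event$termination_s + 1e-6))
    stop("lvf_window must lie within the event", call. = FALSE)
  high <- min(200, 0.45 * x$fs)
  bp <- bandpass_bessel(x, 2, high)
  seg <- function(a, b) bp$samples[.t2i(bp, a):(.t2i(bp, b) - 1L)]
  sd_lvf <- stats::sd(seg(start, start + len))
  sd_pre <- stats::sd(seg(start - len, start))
  structure(list(lvf_start_s = start, lvf_length_s = len, sd_lvf = sd_lvf,
                 sd_preceding = sd_pre,
                 normalized_sd_pct = 100 * sd_lvf / sd_pre),
            class = "lvf_metrics")
}

# --- in-vitro field-potential detectors -----------------------------------

# robust baseline removal: subtract a running median wide enough that a
# single event never dominates the window, so slow 1/f drift does not
# shift event peaks or inflate the background estimate
.detrend <- function(x, fs, width_s) {
  k <- max(3L, round(width_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  x - stats::runmed(x, k)
}

# unimodal field-potential events: suprathreshold bumps of the smoothed
# rectified signal, base duration estimated as 2 x FWHM (exact for the
# raised-cosine waveforms the generator plants, robust for any unimodal bump)
.fp_events <- function(x, fs, peak_thr, smooth_s = 0.01, merge_gap_s = 0.05) {
  k <- max(1L, round(smooth_s * fs))
  sm <- as.numeric(stats::filter(abs(x), rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  supra <- sm > peak_thr
  if (!any(supra)) return(data.frame(onset = numeric(0), term = numeric(0),
                                     peak = numeric(0), base = numeric(0)))
  r <- rle(supra); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by < merge_gap
  if (nrow(runs) > 1) {
    keep <- c(TRUE, (runs[-1, 1] - runs[-nrow(runs), 2]) / fs > merge_gap_s)
    gid <- cumsum(keep)
    runs <- t(vapply(unique(gid), function(g)
      c(min(runs[gid == g, 1]), max(runs[gid == g, 2])), numeric(2)))
  }
  out <- lapply(seq_len(nrow(runs)), function(i) {
    seg <- runs[i, 1]:runs[i, 2]
    ipk <- seg[which.max(sm[seg])]
    half <- sm[ipk] / 2
    l <- ipk; while (l > 1 && sm[l - 1] > half) l <- l - 1
    rgt <- ipk; while (rgt < length(sm) && sm[rgt + 1] > half) rgt <- rgt + 1
    fwhm <- (rgt - l + 1) / fs
    base <- 2 * fwhm
    tpk <- (ipk - 1) / fs
    data.frame(onset = tpk - base / 2, term = tpk + base / 2,
               peak = max(abs(x[seg])), base = base)
  })
  do.call(rbind, out)
}

.drop_excluded <- function(df, exclude) {
  if (is.null(exclude) || !nrow(df) || !length(exclude)) return(df)
  bad <- rep(FALSE, nrow(df))
  for (iv in exclude)
    bad <- bad | (df$onset < iv[2] & df$term > iv[1])
  df[!bad, , drop = FALSE]
}

# incidence gate: keep an event only if the local incidence, counted in a
# data segment of `segment_s` centred on it (clipped at the trace bounds),
# falls inside `range` (events/s)
.incidence_gate <- function(df, total_s, segment_s, range) {
  if (!nrow(df)) return(df)
  ctr <- (df$onset + df$term) / 2
  ok <- vapply(ctr, function(t) {
    a <- max(0, t - segment_s / 2); b <- min(total_s, t + segment_s / 2)
    inc <- sum(ctr >= a & ctr <= b) / (b - a)
    inc >= range[1] && inc <= range[2]
  }, logical(1))
  df[ok, , drop = FALSE]
}

#' Detect in-vitro sharp waves
#'
#' Sharp waves are rhythmic field events with amplitudes about
#' `amplitude_factor` (default 2) times background, base durations of
#' 20-200 ms, and incidences of 0.3-4 events/s measured over 1-min
#' segments.
#'
#' @param x A slice `trace` (single channel).
#' @param amplitude_factor Peak threshold in background-SD multiples.
#' @param width_range Accepted base-duration range, seconds.
#' @param incidence_range Accepted incidence range, events/s.
#' @param exclude Optional list of `c(from, to)` intervals (e.g. ictal
#'   extents) whose events are discarded.
#' @return An [event_table()] with `kind = "SPW"`.
#' @export
detect_spw <- function(x, amplitude_factor = 2, width_range = c(0.02, 0.2),
                       incidence_range = c(0.3, 4), exclude = NULL) {
  stopifnot(inherits(x, "trace"))
  if (duration(x) < 60)
    warning("trace shorter than 60 s; incidence measured over full length",
            call. = FALSE)
  y <- .detrend(x$samples, x$fs, 4 * width_range[2])
  # background amplitude: the ~95th-percentile envelope of a Gaussian
  # background (1.96 robust SDs); the "2x background signals" rule
  # references this amplitude, not the SD
  bg <- 1.96 * stats::mad(y)
  df <- .fp_events(y, x$fs, amplitude_factor * bg, smooth_s = 0.008)
  df <- df[df$base >= width_range[1] & df$base <= width_range[2], , drop = FALSE]
  df <- .drop_excluded(df, exclude)
  df <- .incidence_gate(df, duration(x), min(60, duration(x)), incidence_range)
  event_table(seq_len(nrow(df)), rep(x$channel, nrow(df)), rep("SPW", nrow(df)),
              df$onset + x$t0, df$term + x$t0,
              sprintf('{"peak":%g,"base":%g}', df$peak, df$base))
}

#' Detect interictal spikes
#'
#' Threshold-search detection of interictal field events: amplitudes
#' of at least `amplitude_min_mv` (0.5 mV; the threshold is absolute, so
#' the trace must be in mV), base durations of 200-600 ms, and incidences
#' of 2-5 events per 10 s. The signal is optionally pre-filtered to
#' 0.2-500 Hz (8-pole Bessel, zero phase) before the search.
#'
#' @param x A slice `trace` with `units == "mV"`.
#' @param amplitude_min_mv Absolute peak threshold, mV.
#' @param width_range Accepted base-duration range, seconds.
#' @param incidence_range Accepted incidence range, events per 10 s.
#' @param prefilter Apply the 0.2-500 Hz band-pass first (default TRUE;
#'   the upper corner is capped below Nyquist for low sampling rates).
#' @param exclude Optional exclusion intervals as in [detect_spw()].
#' @return An [event_table()] with `kind = "interictal"`.
#' @export
detect_interictal <- function(x, amplitude_min_mv = 0.5,
                              width_range = c(0.2, 0.6),
                              incidence_range = c(2, 5), prefilter = TRUE,
                              exclude = NULL) {
  stopifnot(inherits(x, "trace"))
  if (!identical(x$units, "mV"))
    stop("interictal detection uses an absolute 0.5 mV rule; trace units must be mV",
         call. = FALSE)
  y <- if (prefilter) bandpass_bessel(x, 0.2, min(500, 0.45 * x$fs)) else x
  z <- .detrend(y$samples, x$fs, 4 * width_range[2])
  df <- .fp_events(z, x$fs, amplitude_min_mv, smooth_s = 0.01)
  df <- df[df$base >= width_range[1] & df$base <= width_range[2], , drop = FALSE]
  df <- .drop_excluded(df, exclude)
  # incidence_range is events per 10 s; the gate works in events/s
  df <- .incidence_gate(df, duration(x), min(10, duration(x)),
                        incidence_range / 10)
  event_table(seq_len(nrow(df)), rep(x$channel, nrow(df)), rep("interictal", nrow(df)),
              df$onset + x$t0, df$term + x$t0,
              sprintf('{"peak":%g,"base":%g}', df$peak, df$base))
}

#' Detect in-vitro ictal discharges
#'
#' Ictal discharges are prolonged self-sustained events with peak
#' amplitudes of at least 1 mV. Suprathreshold spikes are grouped into
#' bursts (gaps below `merge_gap_s` merge); bursts shorter than
#' `min_event_s` are discarded. The trace is classified as ictal-bearing
#' when the detected events' mean duration is >= 30 s and their mean
#' inter-event interval is >= 90 s (trivially satisfied for a single
#' event).
#'
#' @param x A slice `trace` with `units == "mV"`.
#' @param amplitude_min_mv Peak threshold, mV (default 1).
#' @param merge_gap_s Burst grouping gap, seconds.
#' @param min_event_s Minimum burst duration, seconds.
#' @param mean_duration_min_s,mean_iei_min_s Classification thresholds.
#' @return An [event_table()] with `kind = "ICTAL"` and attribute
#'   `ictal_bearing` (logical).
#' @export
detect_ictal_invitro <- function(x, amplitude_min_mv = 1, merge_gap_s = 10,
                                 min_event_s = 5, mean_duration_min_s = 30,
                                 mean_iei_min_s = 90) {
  stopifnot(inherits(x, "trace"))
  if (!identical(x$units, "mV"))
    stop("ictal detection uses an absolute 1 mV rule; trace units must be mV",
         call. = FALSE)
  pk <- .spike_peaks(x$samples, x$fs,
                     rep(amplitude_min_mv, length(x$samples)))$time + x$t0
  if (!length(pk)) {
    out <- event_table()
    attr(out, "ictal_bearing") <- FALSE
    return(out)
  }
  grp <- cumsum(c(1, diff(pk) > merge_gap_s))
  on <- tapply(pk, grp, min) - 0.1
  off <- tapply(pk, grp, max) + 0.2
  keep <- (off - on) >= min_event_s
  on <- on[keep]; off <- off[keep]
  out <- event_table(seq_along(on), rep(x$channel, length(on)), rep("ICTAL", length(on)),
                     as.numeric(on), as.numeric(off))
  bearing <- length(on) > 0 && mean(off - on) >= mean_duration_min_s &&
    (length(on) < 2 || mean(diff(sort(on))) >= mean_iei_min_s)
  attr(out, "ictal_bearing") <- bearing
  out
}

#' Joint slice-event detection
#'
#' Runs the ictal detector first, masks the ictal extents (plus a 2-s
#' guard), then runs the sharp-wave and interictal detectors on the
#' remainder, so burst spikes inside ictal discharges are not double
#' counted as SPWs or interictal events.
#'
#' @param x A slice `trace` with `units == "mV"`.
#' @param ... Passed on to the individual detectors.
#' @return `list(spw, interictal, ictal, ictal_bearing)`.
#' @export
detect_slice_events <- function(x, ...) {
  ict <- detect_ictal_invitro(x)
  excl <- if (nrow(ict))
    lapply(seq_len(nrow(ict)),
           function(i) c(ict$onset_s[i] - 2, ict$termination_s[i] + 2))
  else NULL
  list(spw = detect_spw(x, exclude = excl, ...),
       interictal = detect_interictal(x, exclude = excl),
       ictal = ict,
       ictal_bearing = attr(ict, "ictal_bearing"))
}

#' Peri-ictal epoch segmentation
#'
#' Splits the neighbourhood of one discharge into the five standard
#' peri-ictal segments: preictal `[onset-8, onset)`, onset
#' `[onset, onset+8)`, ictal `[onset+8, term-8)` (the entire discharge
#' excluding onset and offset segments), offset `[term-8, term)`, and
#' postictal `[term, term+8)`. Segments are 8 s long so that each holds at
#' least two 4-s coupling windows. Intervals are truncated at the trace
#' boundaries (flagged), and the middle ictal segment is empty (flagged)
#' for events shorter than 16 s.
#'
#' @param event A detected event row (needs `onset_s`, `termination_s`).
#' @param trace_extent `c(t_start, t_end)` of the available trace, seconds.
#' @param segment_s Segment length (default 8 s).
#' @return A `data.frame`: `segment`, `start_s`, `end_s`, `truncated`,
#'   `empty`, in peri-ictal order.
#' @export
segment_epochs <- function(event, trace_extent, segment_s = 8) {
  on <- event$onset_s; term <- event$termination_s
  stopifnot(is.finite(on), is.finite(term), term > on)
  raw <- data.frame(
    segment = c("preictal", "onset", "ictal", "offset", "postictal"),
    start_s = c(on - segment_s, on, on + segment_s, term - segment_s, term),
    end_s = c(on, on + segment_s, term - segment_s, term, term + segment_s),
    stringsAsFactors = FALSE)
  start_cl <- pmax(raw$start_s, trace_extent[1])
  end_cl <- pmin(raw$end_s, trace_extent[2])
  raw$truncated <- start_cl > raw$start_s | end_cl < raw$end_s
  raw$start_s <- start_cl; raw$end_s <- pmax(end_cl, start_cl)
  raw$empty <- raw$end_s <= raw$start_s
  raw
}
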
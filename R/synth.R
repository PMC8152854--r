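# Synthetic LFP/EEG generator: background noise, seizure discharges with
# LVF/HYP/incremental onsets, cross-frequency coupled signals, phase-locked
# channel pairs, slice field-potential events and movement artifacts --
# each returned together with exact ground truth so detectors and coupling
# estimators can be benchmarked without real recordings.

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic recording configuration
#'
#' @param duration Trace duration, seconds (> 0).
#' @param fs Sampling rate, Hz (default 5000, the acquisition rate the
#'   pipeline is designed around).
#' @param seed Integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @param background_sd Standard deviation of the background noise, volts
#'   (or whatever unit the trace declares).
#' @param spectral_exponent Exponent alpha of the 1/f^alpha background
#'   power spectrum (default 1, an LFP-like broadband floor).
#' @param units,channel Trace metadata.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration, fs = 5000, seed = 1, background_sd = 1,
                         spectral_exponent = 1, units = "uV",
                         channel = "ch1") {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  structure(list(duration = duration, fs = fs, seed = as.integer(seed),
                 background_sd = background_sd,
                 spectral_exponent = spectral_exponent,
                 units = units, channel = channel),
            class = "synth_config")
}

# colored gaussian noise, exact target sd, zero mean; the FFT runs at a
# 2-3-5-smooth length (awkward lengths make R's mixed-radix FFT crawl)
.colored_noise <- function(n, fs, sd_target, alpha) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  if (alpha != 0) {
    W <- stats::fft(w)
    f <- c(0, seq_len(m - 1)) * fs / m
    f[f > fs / 2] <- fs - f[f > fs / 2]        # fold to physical frequency
    h <- c(0, f[-1]^(-alpha / 2))              # kill DC, shape the rest
    w <- Re(stats::fft(W * h, inverse = TRUE)) / m
  }
  w <- w[seq_len(n)]
  w <- w - mean(w)
  w * sd_target / stats::sd(w)
}

#' Generate background trace
#'
#' Draws zero-mean Gaussian noise spectrally shaped to `1/f^alpha` and
#' rescaled so the sample SD equals `background_sd` exactly. This is the
#' broadband floor every amplitude rule downstream (e.g. the "2x
#' background" discharge criterion) is referenced to.
#'
#' @param config A [synth_config()].
#' @return A `trace`.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$duration * config$fs)
  x <- .with_seed(config$seed,
                  .colored_noise(n, config$fs, config$background_sd,
                                 config$spectral_exponent))
  trace(x, config$fs, config$channel, config$units)
}

# biphasic spike template: difference of Gaussians, peak amplitude 1
.spike_template <- function(fs, width_s = 0.06) {
  s1 <- width_s / 6
  s2 <- width_s / 3.5
  t <- seq(-width_s, width_s, by = 1 / fs)
  w <- exp(-t^2 / (2 * s1^2)) - 0.6 * exp(-(t - width_s / 5)^2 / (2 * s2^2))
  w / max(abs(w))
}

# add template-shaped spikes at given times with given peak amplitudes
.add_spikes <- function(x, fs, t0, times, amps, width_s = 0.06) {
  tpl <- .spike_template(fs, width_s)
  half <- (length(tpl) - 1L) %/% 2L
  n <- length(x)
  for (k in seq_along(times)) {
    i <- round((times[k] - t0) * fs) + 1L
    lo <- max(1L, i - half); hi <- min(n, i + half)
    if (lo > hi) next
    x[lo:hi] <- x[lo:hi] + amps[k] * tpl[(lo - i + half + 1L):(hi - i + half + 1L)]
  }
  x
}

#' Discharge specification
#'
#' Parameters of one planted electrographic discharge. Durations are >= 10 s
#' (the recognition rule for spontaneous discharges), LVF windows are
#' 0.5-5 s long with attenuation at or below the 65% criterion by default,
#' and spike amplitudes are expressed in multiples of the background SD
#' (>= 2, the amplitude rule).
#'
#' @param onset_time Discharge onset, seconds.
#' @param total_duration Onset-to-spike-cessation duration, seconds (>= 10).
#' @param onset_class `"LVF"`, `"HYP"` or `"INCREMENTAL"`.
#' @param lvf_attenuation LVF window SD as a fraction of the preceding
#'   signal SD (LVF only).
#' @param lvf_length LVF window length, seconds, in \[0.5, 5\].
#' @param spike_rate Sustained spike rate, events/s.
#' @param spike_amplitude Spike peak amplitude in background-SD units (>= 2).
#' @param suppression_length Post-termination suppression length, seconds.
#' @return A `discharge_spec` list.
#' @export
discharge_spec <- function(onset_time, total_duration = 30,
                           onset_class = c("LVF", "HYP", "INCREMENTAL"),
                           lvf_attenuation = 0.4, lvf_length = 2,
                           spike_rate = 6, spike_amplitude = 8,
                           suppression_length = 3) {
  onset_class <- match.arg(onset_class)
  if (total_duration < 10)
    stop("total_duration must be >= 10 s (discharge recognition rule)", call. = FALSE)
  if (onset_class == "LVF" && (lvf_length < 0.5 || lvf_length > 5))
    stop("lvf_length must be in [0.5, 5] s", call. = FALSE)
  if (spike_amplitude < 2)
    stop("spike_amplitude must be >= 2 background SDs", call. = FALSE)
  structure(list(onset_time = onset_time, total_duration = total_duration,
                 onset_class = onset_class, lvf_attenuation = lvf_attenuation,
                 lvf_length = lvf_length, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude,
                 suppression_length = suppression_length),
            class = "discharge_spec")
}

#' Inject a discharge into a trace
#'
#' Plants one discharge according to `spec`:
#' * `LVF`: the background inside the LVF window is attenuated to
#'   `lvf_attenuation` times its level, then the rhythmic spike train starts;
#' * `HYP`: a cluster of large spikes arises abruptly from baseline (at
#'   least 4 in the first second);
#' * `INCREMENTAL`: spike rate and amplitude ramp up from baseline over the
#'   first 5 s.
#'
#' The sustained section is an inhomogeneous-Poisson spike train of
#' biphasic (difference-of-Gaussians) spikes at `spike_rate` events/s and
#' `spike_amplitude` background SDs; spike cessation is followed by a
#' suppression window in which the background is scaled down to 30%.
#'
#' @param x A `trace` (typically from [generate_background()]).
#' @param spec A [discharge_spec()].
#' @param seed RNG seed for the spike-train draw.
#' @return `list(trace, event)` where `event` is a one-row ground-truth
#'   [event_table()] (`kind = "discharge"`, exact onset/termination, class
#'   and LVF parameters in `params_json`).
#' @export
inject_discharge <- function(x, spec, seed = 1) {
  stopifnot(inherits(x, "trace"), inherits(spec, "discharge_spec"))
  on0 <- spec$onset_time
  term <- on0 + spec$total_duration
  if (on0 < x$t0 + 5 || term + spec$suppression_length > x$t0 + duration(x))
    stop("discharge window (plus 5 s lead-in) must fit inside the trace", call. = FALSE)
  prev <- attr(x, "planted_discharges")
  if (!is.null(prev) &&
      any(on0 < prev$termination_s + 1 & term > prev$onset_s - 1))
    stop("discharge overlaps a previously injected discharge", call. = FALSE)

  fs <- x$fs
  bg_sd <- stats::mad(x$samples) * 1  # mad already scaled to SD for gaussians
  s <- x$samples
  idx <- function(t) .t2i(x, t)

  spike_start <- on0
  if (spec$onset_class == "LVF") {
    i0 <- idx(on0); i1 <- idx(on0 + spec$lvf_length) - 1L
    # scale against the measured SD of the preceding 5 s so the planted
    # attenuation ratio is exact despite the slow 1/f amplitude wander
    sd_pre <- stats::sd(s[idx(on0 - 5):(i0 - 1L)])
    s[i0:i1] <- s[i0:i1] * spec$lvf_attenuation * sd_pre / stats::sd(s[i0:i1])
    spike_start <- on0 + spec$lvf_length
  }

  s <- .with_seed(seed, {
    times <- numeric(0); amps <- numeric(0)
    if (spec$onset_class == "HYP") {
      # abrupt cluster: 4 large spikes in the first 0.9 s
      tc <- spike_start + c(0.05, 0.3, 0.55, 0.8)
      times <- c(times, tc); amps <- c(amps, rep(spec$spike_amplitude, 4))
    }
    if (spec$onset_class == "LVF") {
      # spikes begin promptly once the LVF window ends
      times <- c(times, spike_start + 0.06)
      amps <- c(amps, spec$spike_amplitude)
    }
    ramp_end <- spike_start +
      if (spec$onset_class == "INCREMENTAL") 5 else 0.5
    t <- spike_start
    while (t < term - 0.1) {
      frac <- if (t < ramp_end && spec$onset_class == "INCREMENTAL")
        0.2 + 0.8 * (t - spike_start) / (ramp_end - spike_start) else 1
      rate <- spec$spike_rate * max(frac, 0.2)
      t <- t + stats::rexp(1, rate)
      if (t >= term - 0.05) break
      amp <- spec$spike_amplitude * frac * stats::runif(1, 0.85, 1.15)
      if (spec$onset_class != "INCREMENTAL") amp <- max(amp, 2.2)
      times <- c(times, t); amps <- c(amps, amp * sample(c(1, 1, 1, -1), 1))
    }
    # guarantee a spike near termination so duration is exact
    times <- c(times, term - 0.08); amps <- c(amps, spec$spike_amplitude)
    .add_spikes(s, fs, x$t0, times, amps * bg_sd)
  })

  # post-termination suppression
  j0 <- idx(term); j1 <- idx(term + spec$suppression_length) - 1L
  s[j0:j1] <- s[j0:j1] * 0.3

  out <- trace(s, fs, x$channel, x$units, x$t0)
  ev <- event_table(
    event_id = if (is.null(prev)) 1L else max(prev$event_id) + 1L,
    channel = x$channel, kind = "discharge",
    onset_s = on0, termination_s = term,
    params_json = sprintf(
      '{"onset_class":"%s","lvf_attenuation":%g,"lvf_length":%g,"spike_amplitude":%g}',
      spec$onset_class, spec$lvf_attenuation, spec$lvf_length,
      spec$spike_amplitude))
  attr(out, "planted_discharges") <- rbind(prev, ev)
  list(trace = out, event = ev)
}

#' Inject a short spike burst (negative control)
#'
#' Plants a plain rhythmic spike burst with no LVF window and no
#' suppression, of any duration. Bursts shorter than 10 s are the canonical
#' negative control for the discharge detector's minimum-duration rule.
#'
#' @param x A `trace`.
#' @param onset_time Burst start, seconds.
#' @param burst_duration Burst length, seconds (any positive value).
#' @param spike_rate Spikes per second.
#' @param spike_amplitude Peak amplitude in background-SD multiples.
#' @param seed RNG seed.
#' @return `list(trace, event)` with the ground-truth row (`kind = "burst"`).
#' @export
inject_burst <- function(x, onset_time, burst_duration, spike_rate = 6,
                         spike_amplitude = 8, seed = 1) {
  stopifnot(inherits(x, "trace"), burst_duration > 0)
  bg_sd <- stats::mad(x$samples)
  term <- onset_time + burst_duration
  s <- .with_seed(seed, {
    times <- onset_time
    repeat {
      tn <- times[length(times)] + stats::rexp(1, spike_rate)
      if (tn >= term - 0.05) break
      times <- c(times, tn)
    }
    times <- c(times, term - 0.08)
    amps <- spike_amplitude * stats::runif(length(times), 0.9, 1.1)
    .add_spikes(x$samples, x$fs, x$t0, times, amps * bg_sd)
  })
  ev <- event_table(1L, x$channel, "burst", onset_time, term,
                    sprintf('{"spike_amplitude":%g}', spike_amplitude))
  list(trace = trace(s, x$fs, x$channel, x$units, x$t0), event = ev)
}

#' Cross-frequency coupling specification
#'
#' @param f_phase Slow (phase-giving) frequency, Hz, in \[1, 30\].
#' @param f_amp Fast (amplitude-modulated) frequency, Hz, in \[32, 512\].
#' @param depth Modulation depth in \[0, 1\]: 0 = envelope independent of
#'   phase, 1 = envelope vanishes at the anti-preferred phase.
#' @param carrier_amplitude Carrier amplitude, volts.
#' @param slow_amplitude Slow-oscillation amplitude, volts.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(f_phase = 8, f_amp = 80, depth = 1,
                          carrier_amplitude = 1, slow_amplitude = 2) {
  stopifnot(f_phase >= 1, f_phase <= 30, f_amp >= 32, f_amp <= 512,
            depth >= 0, depth <= 1)
  structure(list(f_phase = f_phase, f_amp = f_amp, depth = depth,
                 carrier_amplitude = carrier_amplitude,
                 slow_amplitude = slow_amplitude),
            class = "coupling_spec")
}

#' Generate a phase-amplitude coupled signal
#'
#' Builds `slow + modulated carrier + background`: a slow cosine at
#' `f_phase` plus a carrier at `f_amp` whose envelope is
#' `(1 - depth) + depth * (1 + cos(phi_slow)) / 2` (maximal at the slow
#' oscillation's peak), plus 1/f background noise from `config`.
#'
#' @param coupling A [coupling_spec()].
#' @param config A [synth_config()]; `config$fs` must exceed `2 * f_amp`.
#' @return `list(trace, truth)` with `truth = c(f_phase, f_amp, depth)`.
#' @export
generate_pac_signal <- function(coupling, config) {
  stopifnot(inherits(coupling, "coupling_spec"), inherits(config, "synth_config"))
  if (coupling$f_amp >= config$fs / 2)
    stop("f_amp must be below fs/2 (aliasing)", call. = FALSE)
  n <- round(config$duration * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  phi <- 2 * pi * coupling$f_phase * t
  env <- (1 - coupling$depth) + coupling$depth * (1 + cos(phi)) / 2
  sig <- coupling$slow_amplitude * cos(phi) +
    coupling$carrier_amplitude * env * cos(2 * pi * coupling$f_amp * t)
  noise <- .with_seed(config$seed,
                      .colored_noise(n, config$fs, config$background_sd,
                                     config$spectral_exponent))
  list(trace = trace(sig + noise, config$fs, config$channel, config$units),
       truth = list(f_phase = coupling$f_phase, f_amp = coupling$f_amp,
                    depth = coupling$depth))
}

#' Generate a phase-locked channel pair
#'
#' Both traces contain a shared narrow-band component (band-pass filtered
#' Gaussian noise around `band_center`) scaled by `lock_fraction`, plus
#' independent background noise scaled by `1 - lock_fraction`. The second
#' channel carries the shared component at 80% amplitude. With
#' `lock_fraction = 1` the traces differ only by that constant amplitude
#' factor, so downstream wavelet phase coherence at `band_center` is 1;
#' with `lock_fraction = 0` the pair is fully independent.
#'
#' @param band_center Center of the shared band, Hz (< fs/2).
#' @param lock_fraction Shared-component weight in \[0, 1\].
#' @param config A [synth_config()].
#' @param rel_bandwidth Shared-band relative bandwidth (default 0.2).
#' @return `list(a, b)` of two `trace` objects.
#' @export
generate_coherent_pair <- function(band_center, lock_fraction, config,
                                   rel_bandwidth = 0.2) {
  stopifnot(inherits(config, "synth_config"),
            lock_fraction >= 0, lock_fraction <= 1)
  if (band_center >= config$fs / 2) stop("band_center must be below fs/2", call. = FALSE)
  n <- round(config$duration * config$fs)
  .with_seed(config$seed, {
    shared_raw <- stats::rnorm(n)
    bw <- band_center * rel_bandwidth / 2
    bf <- signal::butter(4, c(band_center - bw, band_center + bw) / (config$fs / 2),
                         type = "pass")
    shared <- signal::filtfilt(bf, shared_raw)
    shared <- shared / stats::sd(shared) * config$background_sd
    n1 <- .colored_noise(n, config$fs, config$background_sd, config$spectral_exponent)
    n2 <- .colored_noise(n, config$fs, config$background_sd, config$spectral_exponent)
    a <- lock_fraction * shared + (1 - lock_fraction) * n1
    b <- 0.8 * lock_fraction * shared + (1 - lock_fraction) * n2
    list(a = trace(a, config$fs, "chA", config$units),
         b = trace(b, config$fs, "chB", config$units))
  })
}

#' Slice field-potential event specification
#'
#' @param kind `"SPW"`, `"INTERICTAL"` or `"ICTAL"`.
#' @param amplitude_mv Peak amplitude in mV (`INTERICTAL`/`ICTAL`; the
#'   recognition rules are absolute: >= 0.5 and >= 1 mV respectively).
#' @param amplitude_rel Peak amplitude in background-SD units (`SPW`; the
#'   rule is ~2x background).
#' @param base_duration Event base duration, seconds (SPW 0.02-0.2 s,
#'   interictal 0.2-0.6 s, ictal tens of seconds).
#' @param rate Event rate, events/s (SPW / interictal trains).
#' @param interevent_interval Ictal inter-event interval, seconds.
#' @param window Optional `c(from, to)` restricting where events are placed.
#' @return A `slice_event_spec` list.
#' @export
slice_event_spec <- function(kind = c("SPW", "INTERICTAL", "ICTAL"),
                             amplitude_mv = NULL, amplitude_rel = NULL,
                             base_duration, rate = NULL,
                             interevent_interval = NULL, window = NULL) {
  kind <- match.arg(kind)
  if (kind == "ICTAL" && is.null(interevent_interval))
    stop("ICTAL events need interevent_interval", call. = FALSE)
  if (kind != "ICTAL" && is.null(rate))
    stop("SPW/INTERICTAL events need a rate", call. = FALSE)
  structure(list(kind = kind, amplitude_mv = amplitude_mv,
                 amplitude_rel = amplitude_rel, base_duration = base_duration,
                 rate = rate, interevent_interval = interevent_interval,
                 window = window),
            class = "slice_event_spec")
}

# Hann bump of total width w (base duration) and unit peak
.hann_bump <- function(fs, w) {
  t <- seq(0, w, by = 1 / fs)
  0.5 * (1 - cos(2 * pi * t / w))
}

#' Generate a slice field-potential trace
#'
#' Builds an extracellular slice recording in mV: low-amplitude background
#' plus planted sharp waves (Hann bumps, 20-200 ms), interictal spikes
#' (larger Hann bumps, 200-600 ms) and/or ictal discharges (spike bursts
#' with a slow envelope, >= 1 mV, long durations and long inter-event
#' intervals). Event trains are placed on jittered regular grids and
#' collision-checked; overlapping ictal events are an error.
#'
#' @param specs A list of [slice_event_spec()] objects.
#' @param config A [synth_config()]; `background_sd` is in mV (default
#'   sensible value ~0.05 mV).
#' @return `list(trace, events)`: the trace (units `"mV"`) and the
#'   ground-truth [event_table()] (kind, exact onset/termination, amplitude
#'   and width in `params_json`).
#' @export
generate_slice_trace <- function(specs, config) {
  stopifnot(inherits(config, "synth_config"))
  if (inherits(specs, "slice_event_spec")) specs <- list(specs)
  n <- round(config$duration * config$fs)
  fs <- config$fs
  .with_seed(config$seed, {
    x <- .colored_noise(n, fs, config$background_sd, config$spectral_exponent)
    bg_sd <- config$background_sd
    occupied <- matrix(numeric(0), ncol = 2)   # ictal exclusion intervals
    placed <- matrix(numeric(0), ncol = 2)     # every planted event extent
    rows <- list()
    eid <- 0L
    # ictal discharges claim their extents first so brief events never land
    # inside them; rarer brief trains are placed before denser ones so
    # collision skipping does not thin them below their stated incidence
    ord <- order(vapply(specs, function(s)
      if (s$kind == "ICTAL") -1 else s$rate, numeric(1)))
    for (sp in specs[ord]) {
      win <- if (is.null(sp$window)) c(0, config$duration) else sp$window
      if (sp$kind == "ICTAL") {
        starts <- seq(win[1] + sp$interevent_interval / 2,
                      win[2] - sp$base_duration - 1,
                      by = sp$interevent_interval)
        if (length(starts) > 1 &&
            any(diff(starts) < sp$base_duration))
          stop("overlapping ictal events", call. = FALSE)
        for (st in starts) {
          amp <- sp$amplitude_mv
          dur <- sp$base_duration
          tt <- st
          times <- numeric(0)
          while (tt < st + dur - 0.2) {
            times <- c(times, tt)
            tt <- tt + stats::runif(1, 0.25, 0.45)
          }
          envl <- 0.5 + 0.5 * sin(pi * (times - st) / dur)
          x <- .add_spikes(x, fs, 0, times + 0.05, amp * envl *
                             sample(c(1, -1), length(times), TRUE, c(0.8, 0.2)),
                           width_s = 0.1)
          # make sure the peak criterion is met unambiguously
          x <- .add_spikes(x, fs, 0, st + dur / 2, amp, width_s = 0.1)
          occupied <- rbind(occupied, c(st, st + dur))
          placed <- rbind(placed, c(st, st + dur))
          eid <- eid + 1L
          rows[[length(rows) + 1L]] <- event_table(
            eid, config$channel, "ICTAL", st, st + dur,
            sprintf('{"amplitude_mv":%g,"base_duration":%g}', amp, dur))
        }
      } else {
        width <- sp$base_duration
        amp <- if (!is.null(sp$amplitude_mv)) sp$amplitude_mv
               else sp$amplitude_rel * bg_sd
        step <- 1 / sp$rate
        cand <- seq(win[1] + 1, win[2] - width - 1, by = step)
        cand <- cand + stats::runif(length(cand), -0.15 * step, 0.15 * step)
        cand <- pmin(pmax(cand, win[1] + 0.2), win[2] - width - 0.2)
        for (st in cand) {
          # skip events that would collide with ictal extents (0.5 s guard)
          # or any already-planted event (0.2 s guard)
          if (nrow(occupied) &&
              any(st < occupied[, 2] + 0.5 & st + width > occupied[, 1] - 0.5))
            next
          if (nrow(placed) &&
              any(st < placed[, 2] + 0.5 & st + width > placed[, 1] - 0.5))
            next
          placed <- rbind(placed, c(st, st + width))
          bump <- amp * .hann_bump(fs, width)
          i0 <- round(st * fs) + 1L
          i1 <- min(n, i0 + length(bump) - 1L)
          x[i0:i1] <- x[i0:i1] + bump[seq_len(i1 - i0 + 1L)]
          eid <- eid + 1L
          rows[[length(rows) + 1L]] <- event_table(
            eid, config$channel, sp$kind, st, st + width,
            sprintf('{"amplitude_mv":%g,"base_duration":%g,"subthreshold":%s}',
                    amp, width,
                    if (sp$kind == "INTERICTAL" && amp < 0.5) "true"
                    else if (sp$kind == "SPW" &&
                             (width < 0.02 || width > 0.2 ||
                              sp$rate < 0.3 || sp$rate > 4)) "true"
                    else "false"))
        }
      }
    }
    ev <- if (length(rows)) do.call(rbind, rows) else event_table()
    ev <- ev[order(ev$onset_s), , drop = FALSE]
    list(trace = trace(x, fs, config$channel, "mV"), events = ev)
  })
}

#' Inject movement artifacts
#'
#' Adds large, brief transients (half-sine bumps of the stated width) at
#' the given times, with peak amplitude `magnitude` times the trace's
#' robust background SD. These emulate the movement artifacts whose
#' containing PAC windows must be excluded from averaging.
#'
#' @param x A `trace`.
#' @param times Artifact center times, seconds.
#' @param magnitude Peak amplitude in background-SD multiples.
#' @param width Artifact width, seconds.
#' @return `list(trace, times)`; `times` is the ground truth.
#' @export
inject_artifact <- function(x, times, magnitude = 10, width = 0.2) {
  stopifnot(inherits(x, "trace"))
  if (!length(times)) return(list(trace = x, times = numeric(0)))
  if (any(times < x$t0 | times > x$t0 + duration(x)))
    stop("artifact times must lie within the trace", call. = FALSE)
  bg <- stats::mad(x$samples)
  bump <- magnitude * bg * .hann_bump(x$fs, width)
  s <- x$samples
  for (tt in times) {
    i0 <- .t2i(x, tt - width / 2)
    i1 <- min(length(s), i0 + length(bump) - 1L)
    s[i0:i1] <- s[i0:i1] + bump[seq_len(i1 - i0 + 1L)]
  }
  list(trace = trace(s, x$fs, x$channel, x$units, x$t0), times = times)
}
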
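# Simulation benches: self-contained synthetic studies that exercise the
# full pipeline against ground truth. Used by the test suite and by
# scripts/acceptance.R; every bench is a pure function of its seed.

# derive a sub-seed from (seed, index) that always fits a 32-bit integer
.mix_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

# overlap-based matching of detected vs ground-truth events
.match_events <- function(det_on, det_off, gt_on, gt_off) {
  hit_det <- vapply(seq_along(det_on), function(i)
    any(det_on[i] < gt_off & det_off[i] > gt_on), logical(1))
  hit_gt <- vapply(seq_along(gt_on), function(i)
    any(gt_on[i] < det_off & gt_off[i] > det_on), logical(1))
  list(precision = if (length(det_on)) mean(hit_det) else NA_real_,
       recall = if (length(gt_on)) mean(hit_gt) else NA_real_)
}

#' Discharge detection and onset-classification bench
#'
#' Plants `n_events` discharges (durations 15-60 s, alternating LVF and HYP
#' onsets, LVF attenuation 0.30-0.55 over 1-4 s windows, spikes at 8
#' background SDs; signal-to-background amplitude ratio >= 3) across
#' several background traces, runs [detect_discharges()], and scores
#' recall, precision, onset-time error and onset-class agreement against
#' the planted ground truth.
#'
#' @param n_events Number of planted discharges (default 50).
#' @param seed Bench seed.
#' @param fs Sampling rate for the bench traces (default 500 Hz; the
#'   discharge band of interest lies below 200 Hz).
#' @param events_per_trace Discharges per background trace.
#' @return List: `recall`, `precision`, `class_agreement` (over matched
#'   events), `onset_err_s` (vector), `lvf_rel_err` (relative error of the
#'   recovered LVF attenuation per planted LVF event), `n_matched`.
#' @export
bench_discharge_detection <- function(n_events = 50, seed = 1, fs = 500,
                                      events_per_trace = 5) {
  n_traces <- ceiling(n_events / events_per_trace)
  params <- detection_params()
  onset_err <- numeric(0); agree <- logical(0); lvf_rel <- numeric(0)
  n_det <- 0L; n_hit_det <- 0L; n_hit_gt <- 0L; n_gt <- 0L
  eid <- 0L
  for (tr_i in seq_len(n_traces)) {
    k <- min(events_per_trace, n_events - (tr_i - 1L) * events_per_trace)
    plan <- .with_seed(.mix_seed(seed, tr_i), {
      dur <- stats::runif(k, 15, 60)
      att <- stats::runif(k, 0.30, 0.55)
      len <- stats::runif(k, 1, 4)
      list(dur = dur, att = att, len = len)
    })
    onsets <- 30 + cumsum(c(0, plan$dur[-k] + 35))
    total_s <- onsets[k] + plan$dur[k] + 40
    x <- generate_background(synth_config(total_s, fs = fs,
                                          seed = .mix_seed(seed, 500 + tr_i)))
    gt <- list()
    for (e in seq_len(k)) {
      eid <- eid + 1L
      cls <- if (eid %% 2L == 1L) "LVF" else "HYP"
      sp <- discharge_spec(onsets[e], plan$dur[e], cls,
                           lvf_attenuation = plan$att[e],
                           lvf_length = plan$len[e])
      r <- inject_discharge(x, sp, seed = .mix_seed(seed, 1000 + eid))
      x <- r$trace
      gt[[e]] <- data.frame(onset = onsets[e],
                            term = onsets[e] + plan$dur[e],
                            class = cls, att = plan$att[e],
                            lvf_len = plan$len[e])
    }
    gt <- do.call(rbind, gt)
    det <- detect_discharges(x, params)
    m <- .match_events(det$onset_s, det$termination_s, gt$onset, gt$term)
    n_det <- n_det + nrow(det)
    n_hit_det <- n_hit_det + round(m$precision * nrow(det))
    n_hit_gt <- n_hit_gt + round(m$recall * nrow(gt))
    n_gt <- n_gt + nrow(gt)
    for (e in seq_len(nrow(gt))) {
      j <- which(det$onset_s < gt$term[e] & det$termination_s > gt$onset[e])
      if (!length(j)) next
      j <- j[1]
      onset_err <- c(onset_err, abs(det$onset_s[j] - gt$onset[e]))
      agree <- c(agree, det$onset_class[j] == gt$class[e])
      if (gt$class[e] == "LVF") {
        # measurement window ends 0.2 s before the first spike so the
        # spike waveform (and its filter ringing) stays out of the SD
        lm <- quantify_lvf(x, NULL, c(gt$onset[e], gt$lvf_len[e] - 0.2))
        lvf_rel <- c(lvf_rel,
                     abs(lm$normalized_sd_pct / 100 - gt$att[e]) / gt$att[e])
      }
    }
  }
  list(recall = n_hit_gt / n_gt, precision = n_hit_det / max(n_det, 1L),
       class_agreement = mean(agree), onset_err_s = onset_err,
       lvf_rel_err = lvf_rel, n_matched = length(agree))
}

#' Short-burst rejection bench
#'
#' Plants `n` spike bursts shorter than the 10-s discharge rule and counts
#' how many the detector (wrongly) reports.
#'
#' @param n Number of bursts.
#' @param burst_s Burst duration (default 8 s, below the rule).
#' @param seed Bench seed.
#' @param fs Sampling rate.
#' @return Number of detected events (0 = all rejected).
#' @export
bench_short_bursts <- function(n = 10, burst_s = 8, seed = 1, fs = 500) {
  total <- 0L
  for (i in seq_len(n)) {
    x <- generate_background(synth_config(120, fs = fs, seed = .mix_seed(seed, i)))
    r <- inject_burst(x, 50, burst_s, seed = .mix_seed(seed, 50 + i))
    total <- total + nrow(detect_discharges(r$trace))
  }
  total
}

#' Comodulogram parameter-recovery bench
#'
#' Generates a 60-s coupled trace (planted phase frequency 8 Hz, amplitude
#' frequency 80 Hz, depth 1, background at 0.3 carrier units), computes the
#' windowed comodulogram on the standard grids, and reports the argmax
#' location and its distance (in grid steps) from the planted pair.
#'
#' @param seed Bench seed.
#' @param fs Sampling rate (default 1250 Hz, comfortably above twice the
#'   512 Hz amplitude-grid top).
#' @return List: `f_phase_hat`, `f_amp_hat`, `phase_steps_off`,
#'   `amp_steps_off` (grid steps between the argmax and the grid points
#'   bracketing the planted frequencies), `max_mi`.
#' @export
bench_pac_recovery <- function(seed = 1, fs = 1250) {
  ps <- generate_pac_signal(coupling_spec(8, 80, 1),
                            synth_config(60, fs = fs, seed = seed,
                                         background_sd = 0.3))
  pw <- pac_windows(ps$trace)
  cm <- comodulogram(pw)
  am <- which(cm == max(cm), arr.ind = TRUE)[1, ]
  steps_off <- function(grid, hat, truth) {
    lg <- log(grid)
    step <- mean(diff(lg))
    abs(log(hat) - log(truth)) / step
  }
  list(f_phase_hat = pw$phase_grid[am[1]], f_amp_hat = pw$amp_grid[am[2]],
       phase_steps_off = steps_off(pw$phase_grid, pw$phase_grid[am[1]], 8),
       amp_steps_off = steps_off(pw$amp_grid, pw$amp_grid[am[2]], 80),
       max_mi = max(cm))
}

#' Modulation-depth monotonicity bench
#'
#' For each of `n_seeds` noise realisations, computes the MI at the planted
#' (8 Hz, 80 Hz) pair for modulation depths 0, 0.25, 0.5, 0.75, 1 and
#' returns the MI matrix plus sign-test p-values for each adjacent depth
#' increment.
#'
#' @param n_seeds Number of seeds (default 20).
#' @param seed Base seed.
#' @param fs,trace_s Trace parameters.
#' @return List: `mi` (n_seeds x 5 matrix), `depths`, `medians`,
#'   `sign_p` (per adjacent pair, one-sided binomial p for "MI increases").
#' @export
bench_depth_monotonicity <- function(n_seeds = 20, seed = 1, fs = 1250,
                                     trace_s = 30) {
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  mi <- matrix(NA_real_, n_seeds, length(depths))
  for (s in seq_len(n_seeds)) {
    for (d in seq_along(depths)) {
      ps <- generate_pac_signal(coupling_spec(8, 80, depths[d]),
                                synth_config(trace_s, fs = fs,
                                             seed = .mix_seed(seed, s),
                                             background_sd = 0.3))
      sp <- cwt_morlet(ps$trace, c(8, 80))
      mi[s, d] <- modulation_index(Arg(sp$coefficients[, 1]),
                                   Mod(sp$coefficients[, 2]))
    }
  }
  sign_p <- vapply(seq_len(length(depths) - 1), function(d) {
    inc <- sum(mi[, d + 1] > mi[, d])
    stats::binom.test(inc, n_seeds, alternative = "greater")$p.value
  }, numeric(1))
  list(mi = mi, depths = depths, medians = apply(mi, 2, stats::median),
       sign_p = sign_p)
}

#' Null wavelet-phase-coherence bench
#'
#' Across-window coherence of independent white-noise pairs, compared with
#' the analytic small-sample bias `sqrt(pi/(4 n))` over `reps` Monte-Carlo
#' replicates.
#'
#' @param reps Replicates (default 200).
#' @param seed Base seed.
#' @param freq Analysis frequency, Hz.
#' @param trace_s,fs Trace parameters (16 s at 256 Hz gives 19 windows of
#'   8 cycles at 10 Hz).
#' @return List: `mean_rho`, `expected` (analytic), `mc_se`, `n_windows`.
#' @export
bench_wpc_null <- function(reps = 200, seed = 1, freq = 10, trace_s = 16,
                           fs = 256) {
  vals <- vapply(seq_len(reps), function(r) {
    .with_seed(.mix_seed(seed, r), {
      n <- round(trace_s * fs)
      a <- trace(stats::rnorm(n), fs)
      b <- trace(stats::rnorm(n), fs)
      wpc_collapse(wpc(a, b, grid = freq))$rho
    })
  }, numeric(1))
  nw <- floor(trace_s * fs / round(8 / freq * fs))
  list(mean_rho = mean(vals), expected = wpc_null_level(nw),
       mc_se = stats::sd(vals) / sqrt(reps), n_windows = nw)
}

#' In-vitro slice detection bench
#'
#' Builds a 450-s mixed slice trace (sharp waves at 1/s and interictal
#' spikes at 0.3/s in the first 145 s; two 40-s, 1.5-mV ictal discharges
#' 120 s apart in the remainder), runs the joint detector, and scores each
#' event class against ground truth. Also runs the three sub-threshold
#' negative controls (0.4-mV interictal amplitude; 250-ms sharp-wave width;
#' 0.1/s sharp-wave incidence), which must all come back empty.
#'
#' @param seed Bench seed.
#' @param fs Sampling rate (default 1000 Hz).
#' @return List: `spw` / `interictal` (precision, recall), `n_ictal`,
#'   `ictal_bearing`, `n_subthreshold_detected` (sum over the three
#'   negative controls).
#' @export
bench_slice_detection <- function(seed = 1, fs = 1000) {
  cfg <- synth_config(450, fs = fs, seed = seed, background_sd = 0.05)
  specs <- list(
    slice_event_spec("SPW", amplitude_rel = 6, base_duration = 0.05,
                     rate = 1, window = c(0, 145)),
    slice_event_spec("INTERICTAL", amplitude_mv = 0.7, base_duration = 0.3,
                     rate = 0.3, window = c(0, 145)),
    slice_event_spec("ICTAL", amplitude_mv = 1.5, base_duration = 40,
                     interevent_interval = 120, window = c(150, 450)))
  g <- generate_slice_trace(specs, cfg)
  res <- detect_slice_events(g$trace)
  score <- function(det, kind, tol = 0.15) {
    gt <- g$events[g$events$kind == kind, ]
    cd <- (det$onset_s + det$termination_s) / 2
    cg <- (gt$onset_s + gt$termination_s) / 2
    list(precision = if (length(cd)) mean(vapply(cd, function(z)
           any(abs(z - cg) < tol), logical(1))) else NA_real_,
         recall = mean(vapply(cg, function(z)
           any(abs(z - cd) < tol), logical(1))))
  }
  neg1 <- generate_slice_trace(
    list(slice_event_spec("INTERICTAL", amplitude_mv = 0.4,
                          base_duration = 0.3, rate = 0.3)),
    synth_config(120, fs = fs, seed = seed + 1, background_sd = 0.05))
  neg2 <- generate_slice_trace(
    list(slice_event_spec("SPW", amplitude_rel = 6, base_duration = 0.25,
                          rate = 1)),
    synth_config(120, fs = fs, seed = seed + 2, background_sd = 0.05))
  neg3 <- generate_slice_trace(
    list(slice_event_spec("SPW", amplitude_rel = 6, base_duration = 0.05,
                          rate = 0.1)),
    synth_config(300, fs = fs, seed = seed + 3, background_sd = 0.05))
  n_neg <- nrow(detect_interictal(neg1$trace)) +
    nrow(detect_spw(neg2$trace)) +
    suppressWarnings(nrow(detect_spw(neg3$trace)))
  list(spw = score(res$spw, "SPW"),
       interictal = score(res$interictal, "INTERICTAL"),
       n_ictal = nrow(res$ictal), ictal_bearing = res$ictal_bearing,
       n_subthreshold_detected = n_neg)
}

#' Null calibration of the group comparison
#'
#' Simulates `n_studies` coupling-free studies: each subject's value is the
#' mean windowed MI of an uncoupled noise trace, two groups of
#' `n_per_group` subjects are compared with the Mann-Whitney test, and the
#' fraction of studies rejecting at alpha = 0.05 is returned (nominally
#' ~5%).
#'
#' @param n_studies Number of simulated studies (default 200).
#' @param n_per_group Subjects per group (default 5).
#' @param seed Base seed.
#' @return List: `rejection_rate`, `n_studies`.
#' @export
bench_null_calibration <- function(n_studies = 200, n_per_group = 5,
                                   seed = 1) {
  subject_value <- function(s) {
    x <- generate_background(synth_config(12, fs = 256, seed = s,
                                          background_sd = 1))
    sp <- cwt_morlet(x, c(8, 80))
    ph <- Arg(sp$coefficients[, 1]); am <- Mod(sp$coefficients[, 2])
    wlen <- 4 * 256
    mean(vapply(1:3, function(w) {
      i <- ((w - 1) * wlen + 1):(w * wlen)
      modulation_index(ph[i], am[i])
    }, numeric(1)))
  }
  rej <- vapply(seq_len(n_studies), function(st) {
    base <- st * 100L
    g1 <- vapply(seq_len(n_per_group), function(i) subject_value(.mix_seed(seed, base + i)),
                 numeric(1))
    g2 <- vapply(seq_len(n_per_group),
                 function(i) subject_value(.mix_seed(seed, base + 50L + i)), numeric(1))
    compare_groups(g1, g2)$p_value < 0.05
  }, logical(1))
  list(rejection_rate = mean(rej), n_studies = n_studies)
}
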
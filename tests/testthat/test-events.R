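test_that("a planted discharge is recovered with accurate onset and duration", {
  r <- make_discharge_trace(onset = 40, dur = 30, cls = "LVF")
  ev <- detect_discharges(r$trace)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 40), 0.5)
  expect_lt(abs(ev$duration_s - 30), 1)
  expect_identical(ev$onset_class, "LVF")
  expect_true(ev$suppressed)
})

test_that("pure background and flat traces yield no events; NaN is an error", {
  bgr <- generate_background(synth_config(120, fs = 500, seed = 42))
  expect_identical(nrow(detect_discharges(bgr)), 0L)
  flat <- trace(rep(0, 60000), 500)
  expect_identical(nrow(detect_discharges(flat)), 0L)
  bad <- bgr; bad$samples[10] <- NaN
  expect_error(detect_discharges(bad), "NA")
  expect_error(detect_discharges(trace_window(bgr, 0, 10)), "longer")
})

test_that("the >=10 s duration rule rejects short bursts", {
  bgr <- generate_background(synth_config(120, fs = 500, seed = 42))
  r <- inject_burst(bgr, 50, 8)
  expect_identical(nrow(detect_discharges(r$trace)), 0L)
  # a 12-s burst passes the same rule
  r2 <- inject_burst(bgr, 50, 12, seed = 3)
  expect_identical(nrow(detect_discharges(r2$trace)), 1L)
})

test_that("raising the amplitude threshold never adds events", {
  r <- make_discharge_trace(dur = 20, cls = "HYP", seed = 33)
  counts <- vapply(c(1.5, 2, 3, 5, 9), function(f)
    nrow(detect_discharges(r$trace, detection_params(amplitude_factor = f))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("onset classes separate on planted LVF and HYP events", {
  got <- character(0); want <- character(0)
  for (s in 1:6) {
    cls <- c("LVF", "HYP")[(s %% 2) + 1]
    r <- make_discharge_trace(dur = 25, cls = cls, seed = 300 + s,
                              att = 0.45, lvf_len = 2.5)
    ev <- detect_discharges(r$trace)
    if (nrow(ev) == 1) { got <- c(got, ev$onset_class); want <- c(want, cls) }
  }
  expect_gte(mean(got == want), 5 / 6)
})

test_that("weak attenuation (90%) fails the 65% LVF rule", {
  r <- make_discharge_trace(att = 0.9, lvf_len = 2, seed = 55)
  ev <- detect_discharges(r$trace)
  expect_identical(nrow(ev), 1L)
  expect_false(ev$onset_class == "LVF")
})

test_that("LVF quantification reproduces constructed attenuation ratios", {
  # noiseless construction: scaled copies of one noise segment
  set.seed(9)
  fs <- 500
  base <- as.numeric(arima.sim(list(ar = 0.95), 4000)) # band-limited-ish
  x <- trace(c(base, 0.5 * base, base), fs)
  m <- quantify_lvf(x, NULL, c(8, 4))     # the attenuated middle half-window
  expect_gt(m$normalized_sd_pct, 45)
  expect_lt(m$normalized_sd_pct, 55)
  # identical windows: exactly 100%
  y <- trace(rep(base, 3), fs)
  expect_equal(quantify_lvf(y, NULL, c(8, 8))$normalized_sd_pct, 100,
               tolerance = 1e-3)   # filter transients differ at segment edges
  # zero LVF window: 0%
  z <- trace(c(base, rep(0, 4000), base), fs)
  expect_lt(quantify_lvf(z, NULL, c(8.5, 3))$normalized_sd_pct, 2)
  expect_error(quantify_lvf(x, NULL, c(8, 0.3)), "0.5")
  expect_error(quantify_lvf(x, list(onset_s = 20, termination_s = 22),
                            c(8, 2)), "within the event")
})

test_that("LVF recovery tracks planted attenuation with background noise", {
  r <- make_discharge_trace(att = 0.4, lvf_len = 3, seed = 77)
  m <- quantify_lvf(r$trace, NULL, c(40, 2.8))
  expect_lt(abs(m$normalized_sd_pct / 100 - 0.4) / 0.4, 0.2)
})

test_that("peri-ictal segmentation gives the canonical five intervals", {
  seg <- segment_epochs(list(onset_s = 100, termination_s = 160), c(0, 300))
  expect_identical(seg$segment,
                   c("preictal", "onset", "ictal", "offset", "postictal"))
  expect_equal(seg$start_s, c(92, 100, 108, 152, 160))
  expect_equal(seg$end_s, c(100, 108, 152, 160, 168))
  expect_false(any(seg$truncated))
  expect_false(any(seg$empty))
  # partition: consecutive, gap-free from onset-8 to termination+8
  expect_equal(seg$start_s[-1], seg$end_s[-5])
})

test_that("segmentation flags boundary cases", {
  # exactly 16 s: empty middle segment
  s16 <- segment_epochs(list(onset_s = 100, termination_s = 116), c(0, 300))
  expect_true(s16$empty[s16$segment == "ictal"])
  # onset near the trace start: preictal truncated
  s4 <- segment_epochs(list(onset_s = 4, termination_s = 40), c(0, 300))
  expect_true(s4$truncated[s4$segment == "preictal"])
  expect_equal(s4$start_s[1], 0)
  expect_equal(s4$end_s[1], 4)
})

test_that("sharp-wave detection honours amplitude, width and incidence rules", {
  g <- generate_slice_trace(
    list(slice_event_spec("SPW", amplitude_rel = 6, base_duration = 0.05,
                          rate = 1)),
    synth_config(120, fs = 1000, seed = 61, background_sd = 0.05))
  det <- detect_spw(g$trace)
  pr <- pr_overlap(det$onset_s, det$termination_s,
                   g$events$onset_s, g$events$termination_s)
  expect_gte(pr["recall"], 0.95)
  expect_gte(pr["precision"], 0.95)
  expect_warning(detect_spw(trace_window(g$trace, 0, 30)), "60 s")
})

test_that("interictal detection applies the absolute mV rules", {
  g <- generate_slice_trace(
    list(slice_event_spec("INTERICTAL", amplitude_mv = 0.6,
                          base_duration = 0.3, rate = 0.3)),
    synth_config(150, fs = 1000, seed = 62, background_sd = 0.05))
  det <- detect_interictal(g$trace)
  pr <- pr_overlap(det$onset_s, det$termination_s,
                   g$events$onset_s, g$events$termination_s)
  expect_gte(pr["recall"], 0.95)
  expect_gte(pr["precision"], 0.95)
  # wrong units: the 0.5 mV rule cannot apply
  wrong <- g$trace; wrong$units <- "uV"
  expect_error(detect_interictal(wrong), "mV")
  # overlong events are rejected
  g8 <- generate_slice_trace(
    list(slice_event_spec("INTERICTAL", amplitude_mv = 0.7,
                          base_duration = 0.8, rate = 0.3)),
    synth_config(120, fs = 1000, seed = 63, background_sd = 0.05))
  expect_identical(nrow(detect_interictal(g8$trace)), 0L)
})

test_that("in-vitro ictal classification follows the duration and interval rules", {
  g <- generate_slice_trace(
    list(slice_event_spec("ICTAL", amplitude_mv = 1.5, base_duration = 40,
                          interevent_interval = 120)),
    synth_config(300, fs = 1000, seed = 64, background_sd = 0.05))
  det <- detect_ictal_invitro(g$trace)
  expect_identical(nrow(det), 2L)
  expect_true(attr(det, "ictal_bearing"))
  # sub-threshold amplitude: nothing detected
  g08 <- generate_slice_trace(
    list(slice_event_spec("ICTAL", amplitude_mv = 0.8, base_duration = 40,
                          interevent_interval = 120)),
    synth_config(300, fs = 1000, seed = 65, background_sd = 0.05))
  det08 <- detect_ictal_invitro(g08$trace)
  expect_identical(nrow(det08), 0L)
  expect_false(attr(det08, "ictal_bearing"))
  expect_error(detect_ictal_invitro(generate_background(
    synth_config(10, fs = 500, seed = 1))), "mV")
})

test_that("a mixed trace separates interictal and ictal activity", {
  cfg <- synth_config(450, fs = 1000, seed = 66, background_sd = 0.05)
  g <- generate_slice_trace(
    list(slice_event_spec("INTERICTAL", amplitude_mv = 0.7,
                          base_duration = 0.3, rate = 0.3,
                          window = c(0, 145)),
         slice_event_spec("ICTAL", amplitude_mv = 1.5, base_duration = 40,
                          interevent_interval = 120, window = c(150, 450))),
    cfg)
  res <- detect_slice_events(g$trace)
  expect_gt(nrow(res$interictal), 0)
  expect_identical(nrow(res$ictal), 2L)
  # interictal-only trace: ictal table empty, interictal table populated
  g2 <- generate_slice_trace(
    list(slice_event_spec("INTERICTAL", amplitude_mv = 0.7,
                          base_duration = 0.3, rate = 0.3)),
    synth_config(150, fs = 1000, seed = 67, background_sd = 0.05))
  res2 <- detect_slice_events(g2$trace)
  expect_identical(nrow(res2$ictal), 0L)
  expect_gt(nrow(res2$interictal), 0)
  expect_false(res2$ictal_bearing)
})
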
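test_that("background generator hits its SD target and is seed-deterministic", {
  cfg <- synth_config(10, fs = 1000, seed = 7, background_sd = 1)
  x <- generate_background(cfg)
  expect_length(x$samples, 10000)
  expect_gt(sd(x$samples), 0.95)
  expect_lt(sd(x$samples), 1.05)
  expect_lt(abs(mean(x$samples)), 1e-10)
  y <- generate_background(cfg)
  expect_identical(x$samples, y$samples)
  z <- generate_background(synth_config(10, fs = 1000, seed = 8))
  expect_false(identical(x$samples, z$samples))
})

test_that("spectral exponent 1 gives ~16x power ratio between 4 and 64 Hz", {
  x <- generate_background(synth_config(120, fs = 1000, seed = 3,
                                        spectral_exponent = 1))
  pg <- spec.pgram(x$samples, spans = 31, taper = 0, plot = FALSE)
  f <- pg$freq * 1000
  p4 <- mean(pg$spec[abs(f - 4) < 1])
  p64 <- mean(pg$spec[abs(f - 64) < 4])
  expect_gt(p4 / p64, 16 / 1.6)
  expect_lt(p4 / p64, 16 * 1.6)
})

test_that("generator rejects invalid configurations", {
  expect_error(synth_config(-1, fs = 1000), "duration")
  expect_error(synth_config(10, fs = 0), "fs")
  expect_error(discharge_spec(10, total_duration = 8), ">= 10")
  expect_error(discharge_spec(10, onset_class = "LVF", lvf_length = 0.3),
               "lvf_length")
  expect_error(discharge_spec(10, spike_amplitude = 1), "spike_amplitude")
})

test_that("LVF injection attenuates the window SD by the stated factor", {
  r <- make_discharge_trace(att = 0.4, lvf_len = 2)
  x <- r$trace
  i_lvf <- which(time_axis(x) >= 40 & time_axis(x) < 42)
  i_pre <- which(time_axis(x) >= 35 & time_axis(x) < 40)
  ratio <- sd(x$samples[i_lvf]) / sd(x$samples[i_pre])
  expect_gt(ratio, 0.36)
  expect_lt(ratio, 0.44)
})

test_that("HYP injection puts >= 3 large spikes in the first second", {
  r <- make_discharge_trace(cls = "HYP")
  x <- r$trace
  bg <- mad(generate_background(synth_config(120, fs = 500, seed = 11))$samples)
  i <- which(time_axis(x) >= 40 & time_axis(x) < 41)
  supra <- abs(x$samples[i]) > 2 * bg
  n_runs <- sum(diff(c(FALSE, supra)) == 1)
  expect_gte(n_runs, 3)
})

test_that("discharge ground truth records the exact requested extent", {
  r <- make_discharge_trace(dur = 30)
  expect_equal(r$event$onset_s, 40)
  expect_equal(r$event$termination_s - r$event$onset_s, 30)
  # suppression follows termination
  x <- r$trace
  i_sup <- which(time_axis(x) >= 70.3 & time_axis(x) < 72.7)
  i_bg <- which(time_axis(x) >= 20 & time_axis(x) < 30)
  expect_lt(sd(x$samples[i_sup]), sd(x$samples[i_bg]))
})

test_that("overlapping discharge injection is refused", {
  r <- make_discharge_trace()
  expect_error(inject_discharge(r$trace, discharge_spec(50, 20)), "overlap")
})

test_that("PAC generator satisfies its envelope contract", {
  cfg <- synth_config(10, fs = 1000, seed = 2, background_sd = 0)
  t <- (seq_len(10000) - 1) / 1000
  # depth 0: constant envelope
  p0 <- generate_pac_signal(coupling_spec(8, 80, 0), cfg)
  carrier0 <- p0$trace$samples - 2 * cos(2 * pi * 8 * t)
  env0 <- abs(carrier0[abs(cos(2 * pi * 80 * t)) > 0.99])
  expect_lt(diff(range(env0)), 0.05)
  # depth 1: envelope vanishes at the anti-preferred phase
  p1 <- generate_pac_signal(coupling_spec(8, 80, 1), cfg)
  carrier1 <- p1$trace$samples - 2 * cos(2 * pi * 8 * t)
  anti <- which(cos(2 * pi * 8 * t) < -0.999)
  expect_lt(max(abs(carrier1[anti])), 0.01)
  expect_error(generate_pac_signal(coupling_spec(8, 400, 1),
                                   synth_config(1, fs = 700, seed = 1)),
               "aliasing")
})

test_that("coherent pair generator is deterministic and locks at lock_fraction 1", {
  cfg <- synth_config(10, fs = 256, seed = 9)
  p1 <- generate_coherent_pair(10, 1, cfg)
  p2 <- generate_coherent_pair(10, 1, cfg)
  expect_identical(p1$a$samples, p2$a$samples)
  expect_identical(p1$b$samples, p2$b$samples)
  # pure lock: channels differ only by the stated constant amplitude factor
  expect_equal(p1$b$samples, 0.8 * p1$a$samples, tolerance = 1e-12)
})

test_that("slice generator plants events matching the stated statistics", {
  g <- generate_slice_trace(
    list(slice_event_spec("SPW", amplitude_rel = 6, base_duration = 0.05,
                          rate = 1)),
    synth_config(60, fs = 1000, seed = 4, background_sd = 0.05))
  n <- nrow(g$events)
  expect_gte(n, 50)
  expect_lte(n, 62)
  widths <- g$events$termination_s - g$events$onset_s
  expect_true(all(widths >= 0.02 & widths <= 0.2))
})

test_that("ictal spacing arithmetic gives 2 events per 300 s at 120-s intervals", {
  g <- generate_slice_trace(
    list(slice_event_spec("ICTAL", amplitude_mv = 1.5, base_duration = 40,
                          interevent_interval = 120)),
    synth_config(300, fs = 500, seed = 4, background_sd = 0.05))
  expect_identical(nrow(g$events), 2L)
})

test_that("sub-threshold interictal plants are marked in the ground truth", {
  g <- generate_slice_trace(
    list(slice_event_spec("INTERICTAL", amplitude_mv = 0.4,
                          base_duration = 0.3, rate = 0.3)),
    synth_config(60, fs = 500, seed = 4, background_sd = 0.05))
  expect_true(all(grepl('"subthreshold":true', g$events$params_json)))
})

test_that("artifact injection adds the stated transient and nothing else", {
  x <- generate_background(synth_config(30, fs = 500, seed = 6))
  bg <- mad(x$samples)
  r <- inject_artifact(x, times = 12, magnitude = 10, width = 0.2)
  i <- which(time_axis(x) >= 11.9 & time_axis(x) <= 12.3)
  expect_gte(max(r$trace$samples[i]), 10 * bg)
  expect_identical(r$times, 12)
  # empty times: identity
  r0 <- inject_artifact(x, numeric(0))
  expect_identical(r0$trace$samples, x$samples)
  expect_error(inject_artifact(x, 40), "within the trace")
})
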
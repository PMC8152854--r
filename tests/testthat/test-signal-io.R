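test_that("CSV trace round trip preserves samples and metadata", {
  x <- trace(rnorm(1000), fs = 500, channel = "hippoL", units = "mV",
             t0 = 2.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trace(x, p)
  y <- read_trace(p)
  expect_equal(y$samples, x$samples, tolerance = 1e-9)
  expect_equal(y$fs, 500)
  expect_identical(y$channel, "hippoL")
  expect_identical(y$units, "mV")
  expect_equal(y$t0, 2.5)
})

test_that("malformed trace CSV is rejected with a named field", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("units=mV", "channel=c", "1", "2"), p)
  expect_error(read_trace(p), "fs")
  writeLines(c("fs=500", "units=mV", "channel=c", "1", "oops"), p)
  expect_error(read_trace(p), "non-numeric")
})

test_that("EDF round trip is identity within 16-bit quantization", {
  set.seed(1)
  a <- trace(rnorm(2500), fs = 500, channel = "hippo", units = "uV")
  b <- trace(rnorm(2500), fs = 500, channel = "ctx", units = "uV")
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(list(a, b), p)
  back <- read_edf(p)
  expect_length(back, 2)
  expect_identical(back[[1]]$channel, "hippo")
  expect_equal(back[[2]]$fs, 500)
  q <- max(abs(a$samples)) / 32767   # one digital step
  expect_lt(max(abs(back[[1]]$samples - a$samples)), 1.5 * q)
  expect_lt(max(abs(back[[2]]$samples - b$samples)), 1.5 * q)
  # channel selection by label
  y <- read_trace(p, format = "edf", channel = "ctx")
  expect_identical(y$channel, "ctx")
})

test_that("event table round trips through CSV and validates columns", {
  ev <- event_table(1:2, c("a", "a"), c("discharge", "discharge"),
                    c(10, 50), c(40, 80), c('{"x":1}', ""))
  p <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, p)
  back <- read_events(p)
  expect_equal(back$onset_s, ev$onset_s)
  expect_equal(back$kind, ev$kind)
  writeLines("a,b\n1,2", p)
  expect_error(read_events(p), "missing column")
})

test_that("detection params round trip through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  write_detection_params(detection_params(amplitude_factor = 3), p)
  back <- read_detection_params(p)
  expect_equal(back$amplitude_factor, 3)
  expect_equal(back$min_duration_s, 10)
})

test_that("band-pass kills DC, passes mid-band within 10%, rejects out-of-band", {
  fs <- 5000
  t <- seq(0, 4, by = 1 / fs)
  expect_lt(mid_amp(bandpass_bessel(trace(rep(1, length(t)), fs), 2, 200)),
            0.01)
  expect_gt(mid_amp(bandpass_bessel(trace(sin(2 * pi * 50 * t), fs), 2, 200)),
            0.9)
  expect_lt(mid_amp(bandpass_bessel(trace(sin(2 * pi * 50 * t), fs), 2, 200)),
            1.1)
  expect_lt(mid_amp(bandpass_bessel(trace(sin(2 * pi * 1000 * t), fs), 2, 200)),
            0.1)
  expect_error(bandpass_bessel(trace(rnorm(100), 100), 2, 200), "fs/2")
})

test_that("notch removes 60 Hz but leaves 30 Hz essentially untouched", {
  fs <- 5000
  t <- seq(0, 4, by = 1 / fs)
  expect_lt(mid_amp(notch(trace(sin(2 * pi * 60 * t), fs))), 0.1)
  expect_gt(mid_amp(notch(trace(sin(2 * pi * 30 * t), fs))), 0.89)
  z <- notch(trace(rep(0, 1000), 500))
  expect_equal(z$samples, rep(0, 1000))
})

test_that("filters are linear and zero-phase", {
  set.seed(2)
  fs <- 1000
  x <- rnorm(4000); y <- rnorm(4000)
  fx <- bandpass_bessel(trace(x, fs), 2, 200)$samples
  fy <- bandpass_bessel(trace(y, fs), 2, 200)$samples
  fxy <- bandpass_bessel(trace(2 * x + 3 * y, fs), 2, 200)$samples
  expect_equal(fxy, 2 * fx + 3 * fy, tolerance = 1e-8)
  # zero-phase: cross-correlation peak of band-limited input vs output at lag 0
  t <- seq(0, 4, by = 1 / fs)
  s <- sin(2 * pi * 20 * t) + 0.5 * sin(2 * pi * 47 * t)
  out <- bandpass_bessel(trace(s, fs), 2, 200)$samples
  cc <- ccf(s, out, lag.max = 25, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("downsampling respects arithmetic, warns below the analysis band, preserves in-band tones", {
  fs <- 5000
  t <- seq(0, 4, by = 1 / fs)
  x <- trace(sin(2 * pi * 450 * t), fs)
  expect_warning(downsample(x, 5), "Nyquist|analysis band")
  y5 <- suppressWarnings(downsample(x, 5))
  expect_equal(y5$fs, 1000)
  expect_identical(downsample(x, 1), x)
  y <- suppressWarnings(downsample(x, 2.5))
  expect_equal(y$fs, 2000)
  expect_gt(mid_amp(y), 0.95)
  expect_lt(mid_amp(y), 1.05)
  expect_error(downsample(x, 0.5), "factor")
})
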
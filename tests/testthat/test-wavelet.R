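test_that("log grid covers the band with constant ratio and exact endpoints", {
  g <- make_log_grid(0.25, 512, 4)
  expect_length(g, 45)                      # 11 octaves x 4 + 1
  expect_equal(g[1], 0.25)
  expect_equal(g[length(g)], 512)
  expect_lt(diff(range(diff(log(g)))), 1e-12)
  g2 <- make_log_grid(1, 30, 4)
  expect_equal(g2[length(g2)], 30, tolerance = 1e-9)
  expect_equal(as.numeric(make_log_grid(32, 512, 1)), c(32, 64, 128, 256, 512))
  expect_error(make_log_grid(30, 1), "fmin")
})

test_that("a pure tone produces a stable ridge at its own frequency", {
  fs <- 1000
  tr <- trace(cos(2 * pi * 8 * seq(0, 10, by = 1 / fs)), fs)
  g <- make_log_grid(1, 30, 4)
  sp <- cwt_morlet(tr, g)
  A <- extract_amplitude(sp)
  mid <- 3000:7000
  ridge <- which.max(colMeans(A[mid, ]))
  # argmax within one grid step of the tone
  expect_lt(abs(log(sp$grid[ridge]) - log(8)), 1.01 * mean(diff(log(g))))
  # |W| time-constant within 5% away from edges
  expect_lt(diff(range(A[mid, ridge])) / mean(A[mid, ridge]), 0.05)
})

test_that("transform is linear and zero in equals zero out", {
  fs <- 500
  z <- cwt_morlet(trace(rep(0, 2000), fs), c(4, 16))
  expect_true(all(Mod(z$coefficients) == 0))
  set.seed(3)
  x <- rnorm(2000); y <- rnorm(2000)
  Wx <- cwt_morlet(trace(x, fs), c(4, 16))$coefficients
  Wy <- cwt_morlet(trace(y, fs), c(4, 16))$coefficients
  Wxy <- cwt_morlet(trace(2 * x + 3 * y, fs), c(4, 16))$coefficients
  expect_equal(Wxy, 2 * Wx + 3 * Wy, tolerance = 1e-10)
})

test_that("superposed tones give two ridges matching their single-tone runs", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  g <- make_log_grid(2, 128, 4)
  mid <- 3000:7000
  one <- function(f, a) {
    A <- extract_amplitude(cwt_morlet(trace(a * cos(2 * pi * f * t), fs), g))
    colMeans(A[mid, ])
  }
  both <- extract_amplitude(cwt_morlet(
    trace(cos(2 * pi * 4 * t) + 0.5 * cos(2 * pi * 64 * t), fs), g))
  prof <- colMeans(both[mid, ])
  r4 <- one(4, 1); r64 <- one(64, 0.5)
  i4 <- which.min(abs(g - 4)); i64 <- which.min(abs(g - 64))
  expect_equal(prof[i4] / prof[i64], r4[i4] / r64[i64], tolerance = 0.05)
})

test_that("phase is the four-quadrant angle and advances at the tone rate", {
  sp <- structure(list(coefficients = matrix(c(1 + 0i, 0 + 1i, -1 + 0i,
                                               3 + 4i), 2, 2),
                       grid = c(1, 2), fs = 10, t0 = 0, coi_s = c(1, 1)),
                  class = "wavelet_spectrum")
  ph <- extract_phase(sp)
  expect_equal(ph[1, 1], 0)
  expect_equal(ph[2, 1], pi / 2)
  expect_equal(ph[1, 2], pi)
  expect_equal(extract_amplitude(sp)[2, 2], 5)
  fs <- 1000
  tr <- trace(cos(2 * pi * 8 * seq(0, 10, by = 1 / fs)), fs)
  spec <- cwt_morlet(tr, 8)
  mid <- 3000:7000
  up <- signal::unwrap(Arg(spec$coefficients[mid, 1]))
  slope <- coef(lm(up ~ I((mid - 1) / fs)))[[2]] / (2 * pi)
  expect_equal(slope, 8, tolerance = 0.01)
})

test_that("phase is scale-invariant and amplitude scales exactly", {
  set.seed(4)
  fs <- 500
  x <- rnorm(2000)
  W1 <- cwt_morlet(trace(x, fs), c(4, 16))$coefficients
  W3 <- cwt_morlet(trace(3 * x, fs), c(4, 16))$coefficients
  expect_equal(W3, 3 * W1, tolerance = 1e-12)
  expect_equal(Arg(W3), Arg(W1), tolerance = 1e-10)
})

test_that("amplitude of a modulated carrier oscillates at the modulating rate", {
  fs <- 1000
  p <- generate_pac_signal(coupling_spec(8, 80, 1),
                           synth_config(10, fs = fs, seed = 5,
                                        background_sd = 0))
  sp <- cwt_morlet(p$trace, 80)
  env <- Mod(sp$coefficients[2000:8000, 1])
  pg <- spec.pgram(env - mean(env), plot = FALSE)
  expect_equal(pg$freq[which.max(pg$spec)] * fs, 8, tolerance = 0.5)
})

test_that("time shift moves the ridge; cone of influence flags the edges", {
  fs <- 250
  n <- 2500
  x <- numeric(n); x[1000:1050] <- sin(2 * pi * 25 * (0:50) / fs)
  y <- numeric(n); y[1500:1550] <- x[1000:1050]
  Ax <- extract_amplitude(cwt_morlet(trace(x, fs), 25))
  Ay <- extract_amplitude(cwt_morlet(trace(y, fs), 25))
  expect_equal(which.max(Ay[, 1]) - which.max(Ax[, 1]), 500)
  m <- coi_mask(cwt_morlet(trace(x, fs), c(2, 25)))
  expect_true(all(m[1:5, ]))
  expect_false(any(m[1200:1300, ]))
  # slower frequencies have wider contaminated margins
  expect_gt(sum(m[, 1]), sum(m[, 2]))
})

test_that("frequencies at or beyond Nyquist are refused", {
  expect_error(cwt_morlet(trace(rnorm(100), 100), c(10, 50)), "fs/2")
})
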
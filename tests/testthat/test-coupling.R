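test_that("modulation index hits its analytic limits", {
  ph <- seq(-pi + 1e-9, pi, length.out = 3600)
  expect_equal(modulation_index(ph, rep(2, 3600)), 0, tolerance = 1e-12)
  amp <- as.numeric(ph <= -pi + 2 * pi / 18)
  expect_equal(modulation_index(ph, amp), 1, tolerance = 1e-12)
})

test_that("modulation index matches an independent brute-force KL sum", {
  # target distribution: half the mass in one bin, the rest spread evenly
  ph <- seq(-pi + 1e-9, pi, length.out = 3600)
  amp <- ifelse(ph <= -pi + 2 * pi / 18, 0.5 * 17, 0.5)
  got <- modulation_index(ph, amp)
  # brute force: explicit p and KL sum, no shared code path
  p <- c(0.5, rep(0.5 / 17, 17))
  expect_equal(sum(p * log(p / (1 / 18))) / log(18), got, tolerance = 1e-12)
  expect_equal(got, 0.5 * log(81 / 17) / log(18), tolerance = 1e-12)
})

test_that("vectorized MI equals a naive per-sample loop to 1e-12", {
  set.seed(10)
  n <- 1e4
  ph <- runif(n, -pi, pi)
  amp <- abs(rnorm(n)) * (1 + cos(ph))
  naive <- function(phase, amplitude, nb = 18) {
    sums <- numeric(nb); cnts <- numeric(nb)
    for (i in seq_len(length(phase))) {
      k <- min(nb, max(1, ceiling((phase[i] + pi) / (2 * pi / nb))))
      sums[k] <- sums[k] + amplitude[i]
      cnts[k] <- cnts[k] + 1
    }
    p <- ifelse(cnts > 0, sums / cnts, 0)
    p <- p / sum(p)
    s <- 0
    for (k in seq_len(nb)) if (p[k] > 0) s <- s + p[k] * log(p[k] * nb)
    s / log(nb)
  }
  expect_equal(modulation_index(ph, amp), naive(ph, amp), tolerance = 1e-12)
})

test_that("MI is invariant to amplitude rescaling and bin-label permutation", {
  set.seed(11)
  ph <- runif(5000, -pi, pi)
  amp <- abs(rnorm(5000)) * (1 + 0.7 * cos(ph))
  m0 <- modulation_index(ph, amp)
  expect_equal(modulation_index(ph, 37.5 * amp), m0, tolerance = 1e-12)
  # rotating all phases by whole bins permutes bin labels only
  ph_rot <- ph + 2 * pi * 5 / 18
  expect_equal(modulation_index(ph_rot, amp), m0, tolerance = 1e-12)
  expect_true(m0 >= 0 && m0 <= 1)
})

test_that("degenerate amplitude inputs are handled as stated", {
  ph <- runif(100, -pi, pi)
  expect_warning(ret <- modulation_index(ph, rep(0, 100)), "undefined")
  expect_true(is.na(ret))
  expect_error(modulation_index(ph, rep(-1, 100)), "nonnegative")
  expect_error(modulation_index(ph, 1:99), "equal length")
})

test_that("windowed comodulogram recovers a planted coupling pair", {
  p <- bench_pac_recovery(seed = 101)
  expect_lte(p$phase_steps_off, 1)
  expect_lte(p$amp_steps_off, 1)
})

test_that("minimum-cycles rule flags only sub-4-cycle phase rows", {
  x <- generate_background(synth_config(12, fs = 256, seed = 12))
  pw <- pac_windows(x, phase_grid = c(0.5, 1, 8), amp_grid = c(40, 80),
                    window_s = 4)
  expect_identical(pw$reliable_phase, c(FALSE, TRUE, TRUE))
})

test_that("an injected artifact masks exactly its window end to end", {
  x <- generate_background(synth_config(40, fs = 256, seed = 13))
  r <- inject_artifact(x, times = 10, magnitude = 20, width = 0.2)
  pw <- pac_windows(r$trace, phase_grid = c(4, 8), amp_grid = c(40, 80))
  expect_identical(which(pw$excluded), 3L)
  # clean trace: nothing masked; infinite threshold: nothing masked
  pw0 <- pac_windows(x, phase_grid = c(4, 8), amp_grid = c(40, 80))
  expect_false(any(pw0$excluded))
  pw_inf <- pac_windows(r$trace, phase_grid = c(4, 8), amp_grid = c(40, 80),
                        artifact_threshold_sd = Inf)
  expect_false(any(pw_inf$excluded))
})

test_that("segment averaging honours identity and artifact exclusion", {
  x <- generate_background(synth_config(40, fs = 256, seed = 14))
  pw <- pac_windows(x, phase_grid = c(4, 8), amp_grid = c(40, 80))
  seg <- segment_epochs(list(onset_s = 8, termination_s = 32), c(0, 40))
  mp <- mean_pac(pw, seg)
  expect_identical(mp$segment,
                   c("preictal", "onset", "ictal", "offset", "postictal"))
  # identity: a segment's mean equals the mean of its windows' grid means
  wmean <- apply(pw$mi, 1, mean)
  ctr <- pw$starts + 2
  sel <- ctr >= 8 & ctr < 16
  expect_equal(mp$mean_mi[mp$segment == "onset"], mean(wmean[sel]))
  # masking one of two windows leaves the mean over the survivor
  pw2 <- pw
  pw2$excluded[which(sel)[1]] <- TRUE
  mp2 <- mean_pac(pw2, seg)
  expect_equal(mp2$n_windows[mp2$segment == "onset"], sum(sel) - 1)
  pw3 <- pw
  pw3$excluded[ctr >= 0 & ctr < 8] <- TRUE
  expect_true(is.na(mean_pac(pw3, seg)$mean_mi[1]))
})

test_that("MI grows with planted modulation depth (sign test across seeds)", {
  m <- bench_depth_monotonicity(n_seeds = 12, seed = 7, trace_s = 20)
  expect_true(all(diff(m$medians) > 0))
  expect_true(all(m$sign_p < 0.05))
})

test_that("identical inputs give coherence 1 everywhere", {
  x <- generate_background(synth_config(20, fs = 256, seed = 15))
  m <- wpc(x, x, grid = make_log_grid(1, 64, 2))
  rhos <- unlist(lapply(m$windows, `[[`, "rho"))
  expect_true(all(abs(rhos - 1) < 1e-6))
  cc <- wpc_collapse(m)
  expect_true(all(abs(cc$rho - 1) < 1e-6))
})

test_that("coherence is symmetric, scale-invariant and bounded", {
  cfg <- synth_config(16, fs = 128, seed = 16)
  p <- generate_coherent_pair(10, 0.5, cfg)
  m_ab <- wpc(p$a, p$b, grid = c(5, 10, 20))
  m_ba <- wpc(p$b, p$a, grid = c(5, 10, 20))
  r_ab <- unlist(lapply(m_ab$windows, `[[`, "rho"))
  r_ba <- unlist(lapply(m_ba$windows, `[[`, "rho"))
  expect_equal(r_ab, r_ba, tolerance = 1e-12)
  expect_true(all(r_ab >= 0 & r_ab <= 1))
  sc <- trace(5 * p$b$samples, p$b$fs, p$b$channel, p$b$units, p$b$t0)
  r_sc <- unlist(lapply(wpc(p$a, sc, grid = c(5, 10, 20))$windows,
                        `[[`, "rho"))
  expect_equal(r_sc, r_ab, tolerance = 1e-12)
  expect_error(wpc(p$a, trace(rnorm(100), 128)), "share")
})

test_that("a constant-phase, scaled copy stays fully coherent at its tone", {
  fs <- 256
  t <- seq(0, 16, by = 1 / fs)
  a <- trace(cos(2 * pi * 10 * t), fs)
  b <- trace(0.3 * cos(2 * pi * 10 * t - 1.2), fs)
  m <- wpc(a, b, grid = 10)
  r <- m$windows[[1]]$rho
  # edge windows sit inside the cone of influence; judge the interior
  expect_true(all(r[2:(length(r) - 1)] > 1 - 1e-4))
  expect_true(all(r > 0.99))
})

test_that("independent noise coherence sits at the analytic null level", {
  w <- bench_wpc_null(reps = 80, seed = 21)
  expect_lt(abs(w$mean_rho - w$expected), 4 * w$mc_se)
})
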
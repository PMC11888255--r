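test_that("label traces average exactly over their mask pixels", {
  frames <- array(7, dim = c(5, 8, 8))
  mask <- matrix(0L, 8, 8); mask[2:3, 2:3] <- 1L; mask[6:7, 6:7] <- 2L
  ts <- extract_label_traces(frames, mask)
  expect_true(all(ts$traces == 7))
  # two labels with distinct constant intensities
  for (f in 1:5) {
    fr <- matrix(0, 8, 8); fr[mask == 1] <- 3; fr[mask == 2] <- 9
    frames[f, , ] <- fr
  }
  ts2 <- extract_label_traces(frames, mask)
  expect_equal(ts2$traces[1, ], rep(3, 5))
  expect_equal(ts2$traces[2, ], rep(9, 5))
  expect_error(extract_label_traces(frames, matrix(0L, 8, 8)), "label")
})

test_that("rendered movies round-trip through trace extraction", {
  p <- calcium_sim_params(n_units = 4, duration = 10, seed = 6)
  sim <- simulate_calcium_traceset(p)
  mov <- render_calcium_movie(sim$traces, shape = c(48, 48))
  ts <- extract_label_traces(mov$frames, mov$mask, p$frame_rate)
  expect_equal(ts$traces, sim$traces$traces, tolerance = 1e-12)
})

test_that("rolling-median detrending matches a brute-force oracle", {
  set.seed(14)
  x <- cumsum(rnorm(200))
  for (w in c(2, 5, 20, 21)) {
    expect_equal(detrend_rolling_median(x, w)$trend,
                 oracle_rolling_median(x, w), tolerance = 1e-12,
                 info = paste("window", w))
  }
})

test_that("detrending zeroes constants everywhere and affine interiors", {
  const <- rep(4.2, 120)
  expect_true(all(detrend_rolling_median(const, 20)$detrended == 0))
  for (slope in c(2.5, -1.3)) {
    ramp <- 10 + slope * seq_len(150)
    for (w in c(20, 21)) {
      resid <- detrend_rolling_median(ramp, w)$detrended
      interior <- resid[(w + 1):(150 - w)]
      expect_lt(max(abs(interior)), 1e-10)
    }
  }
  # window 1 subtracts the trace from itself
  expect_true(all(detrend_rolling_median(rnorm(30), 1)$detrended == 0))
  expect_error(detrend_rolling_median(rnorm(10), 20), "exceed")
})

test_that("dF/F0 is exactly invariant to multiplicative gain", {
  set.seed(2)
  x <- 100 + 5 * sin(seq(0, 8 * pi, length.out = 400)) + rnorm(400)
  d1 <- dff_pipeline(x, 10)
  for (gain in c(0.01, 7, 1234)) {
    d2 <- dff_pipeline(gain * x, 10)
    expect_equal(d2$dff, d1$dff, tolerance = 1e-13)
  }
  # constant trace maps to all zeros
  expect_true(all(dff_pipeline(rep(50, 100), 10)$dff == 0))
})

test_that("dF/F0 equals residual over trend mean on a hand fixture", {
  trace <- c(10, 10, 10, 14, 10, 10)
  trend <- rep(10, 6)
  d <- compute_dff(trace, trend, frame_rate = 1)
  expect_equal(d$dff, c(0, 0, 0, 0.4, 0, 0))
  expect_error(compute_dff(c(-5, -5), c(-5, -5), 1), "positive")
})

test_that("spike detection finds inserted transients and nothing else", {
  expect_identical(
    detect_calcium_spikes(rep(0, 100) + rnorm(100, 0, 1e-4),
                          frame_rate = 10)$n_spikes >= 0, TRUE)
  # flat trace: zero variance handled as zero spikes
  expect_message(r0 <- detect_calcium_spikes(rep(1, 100), frame_rate = 10),
                 "zero-variance")
  expect_identical(r0$n_spikes, 0L)
  # one 10-SD transient in low noise is exactly one spike
  set.seed(8)
  x <- rnorm(600, 0, 0.01)
  x[300:305] <- x[300:305] + 0.1 * c(0.8, 1, 0.95, 0.8, 0.6, 0.4)
  r <- detect_calcium_spikes(x, frame_rate = 10)
  expect_identical(r$n_spikes, 1L)
  expect_true(abs(r$spike_frames - 300) <= 2)
})

test_that("trace AUC matches geometric and refinement oracles", {
  expect_equal(trace_auc(rep(2, 101), frame_rate = 10), 2 * 10)
  tri <- c(seq(0, 3, length.out = 11), seq(3, 0, length.out = 11)[-1])
  expect_equal(trace_auc(tri, frame_rate = 1), 3 * 20 / 2)
  # smooth trace: trapezoid at 1x vs Riemann sum at 10x resolution
  f <- function(t) 0.4 * sin(t / 3) + 0.5
  coarse <- trace_auc(f((0:300) / 10), frame_rate = 10)
  tfine <- seq(0, 30, by = 0.01)
  fine <- sum(f(tfine)) * 0.01
  expect_lt(abs(coarse - fine) / fine, 0.01)
})

test_that("pairwise mean correlation behaves at its extremes", {
  M <- rbind(sin(1:200), sin(1:200), sin(1:200))
  expect_equal(pairwise_mean_correlation(M), 1)
  set.seed(5)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(pairwise_mean_correlation(rbind(a, b)), cor(a, b))
  N <- matrix(rnorm(4 * 10000), nrow = 4)
  expect_lt(abs(pairwise_mean_correlation(N)), 0.05)
  expect_error(pairwise_mean_correlation(matrix(1:5, nrow = 1)), "2 traces")
})

test_that("power spectra localize tones and conserve variance", {
  fs <- 10
  t <- (0:4095) / fs
  x <- sin(2 * pi * 1.25 * t)
  ps <- power_spectrum(x, frame_rate = fs)
  expect_equal(ps$spectrum$freq_hz[which.max(ps$spectrum$psd)], 1.25,
               tolerance = fs / 256)
  # Parseval: integrated PSD close to the variance of white noise
  set.seed(31)
  n <- rnorm(10000)
  psn <- power_spectrum(n, frame_rate = fs)
  expect_lt(abs(psn$auc - var(n)) / var(n), 0.1)
  # silence in, silence out
  ps0 <- power_spectrum(rep(0, 1000), frame_rate = fs)
  expect_true(all(ps0$spectrum$psd == 0))
  expect_identical(ps0$auc, 0)
})

test_that("the pipeline ignores slow additive drift after detrending", {
  p <- calcium_sim_params(n_units = 1, duration = 120, spike_rate = 2 / 60,
                          drift_amplitude = 0, noise_sd = 0.02, seed = 19)
  sim <- simulate_calcium_traceset(p)
  x <- sim$traces$traces[1, ]
  n1 <- detect_calcium_spikes(dff_pipeline(x, 10))$n_spikes
  drift <- 20 * sin(2 * pi * (0:(length(x) - 1)) / length(x))
  n2 <- detect_calcium_spikes(dff_pipeline(x + drift, 10))$n_spikes
  expect_identical(n1, n2)
})

test_that("per-unit metrics table carries one tidy row per unit", {
  p <- calcium_sim_params(n_units = 6, duration = 60, seed = 23)
  sim <- simulate_calcium_traceset(p, condition = "stimulated")
  m <- calcium_unit_metrics(sim$traces)
  expect_identical(nrow(m), 6L)
  expect_true(all(c("spikes_per_min", "auc", "spectral_auc",
                    "condition") %in% names(m)))
  expect_true(all(m$condition == "stimulated"))
})
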
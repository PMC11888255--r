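# Ground-truth behaviour of the four generators.

test_that("calcium generator degenerates to a constant baseline", {
  p <- calcium_sim_params(n_units = 2, duration = 10, spike_rate = 0,
                          drift_amplitude = 0, noise_sd = 0, seed = 1)
  sim <- simulate_calcium_traceset(p)
  expect_true(all(sim$traces$traces == p$baseline))
  expect_true(all(lengths(sim$spikes) == 0))
})

test_that("a single noise-free transient peaks at baseline * (1 + amplitude)", {
  p <- calcium_sim_params(n_units = 1, duration = 30, drift_amplitude = 0,
                          noise_sd = 0, transient_amplitude = 0.5, seed = 1)
  sim <- simulate_calcium_traceset(p, spike_times = list(10))
  # closed-form kernel maximum over the frame grid
  tt <- (seq_len(300) - 1) / 10
  kmax <- max(calcium_kernel(tt - 10, p$kernel_rise, p$kernel_decay))
  expect_equal(max(sim$traces$traces),
               p$baseline * (1 + p$transient_amplitude * kmax),
               tolerance = 1e-12)
  # discretization keeps the frame peak within a few percent of the true one
  expect_gt(kmax, 0.95)
})

test_that("generators are bit-reproducible given (params, seed)", {
  p <- calcium_sim_params(n_units = 3, duration = 20, seed = 11)
  expect_identical(simulate_calcium_traceset(p)$traces$traces,
                   simulate_calcium_traceset(p)$traces$traces)
  sp <- spine_sim_params(n_segments = 2, seed = 11)
  expect_identical(simulate_spine_trajectory_set(sp)$sizes,
                   simulate_spine_trajectory_set(sp)$sizes)
  mp <- mepsc_sim_params(duration = 2, seed = 11)
  expect_identical(simulate_mepsc_trace(mp)$trace$current,
                   simulate_mepsc_trace(mp)$trace$current)
  cp <- cfos_image_params(n_cells = 4, seed = 11)
  expect_identical(simulate_cfos_stack(cp)$cfos, simulate_cfos_stack(cp)$cfos)
})

test_that("calcium traces stay positive at moderate noise", {
  p <- calcium_sim_params(n_units = 10, duration = 60, noise_sd = 0.2,
                          seed = 5)
  sim <- simulate_calcium_traceset(p)
  expect_true(all(sim$traces$traces > 0))
})

test_that("spine generator is constant without fluctuation, reversion or stim", {
  p <- spine_sim_params(n_segments = 3, reversion_rate = 0,
                        fluctuation_sd = 0, stim_effect_small = 0, seed = 2)
  sim <- simulate_spine_trajectory_set(p, "stimulated")
  spread <- sim$sizes |>
    dplyr::group_by(segment_id, spine_id) |>
    dplyr::summarise(d = diff(range(size_au)), .groups = "drop")
  expect_true(all(spread$d == 0))
})

test_that("adjacent-spine innovation correlation matches the target", {
  p <- spine_sim_params(n_segments = 200, spines_per_segment = 10,
                        spatial_corr_near = 0.6, reversion_rate = 0,
                        stim_effect_small = 0, seed = 8)
  sim <- simulate_spine_trajectory_set(p)
  # innovations are the per-step log-size increments when reversion is off
  incr <- sim$sizes |>
    dplyr::group_by(segment_id, spine_id) |>
    dplyr::arrange(time_h, .by_group = TRUE) |>
    dplyr::mutate(innov = c(NA, diff(log(size_au)))) |>
    dplyr::filter(!is.na(innov)) |>
    dplyr::ungroup()
  adj <- incr |>
    dplyr::inner_join(
      dplyr::mutate(incr, spine_id = spine_id - 1L) |>
        dplyr::select(segment_id, spine_id, time_label, innov2 = innov),
      by = c("segment_id", "spine_id", "time_label"))
  expect_equal(cor(adj$innov, adj$innov2), 0.6, tolerance = 0.05)
})

test_that("the stimulated condition enlarges the smallest size tercile", {
  p <- spine_sim_params(n_segments = 40, stim_effect_small = 0.3, seed = 3)
  d_of <- function(cond) {
    sim <- simulate_spine_trajectory_set(p, cond)
    sizes <- dplyr::inner_join(
      sim$sizes, dplyr::select(sim$truth, segment_id, spine_id, tercile),
      by = c("segment_id", "spine_id"))
    small <- dplyr::filter(sizes, tercile == 1L)
    b <- delta_size_binned(small, "post_24h",
                           bin_edges = max(small$size_au) + 1)
    b$mean_delta[1]
  }
  expect_gt(d_of("stimulated"), d_of("control"))
})

test_that("non-PSD spatial correlation requests fail at construction", {
  expect_error(spine_sim_params(spatial_corr_near = -0.9,
                                spatial_corr_far = 0.9, corr_length = 1),
               class = "tbsquant_config_error")
})

test_that("mEPSC generator obeys its Poisson and kernel contracts", {
  # no events
  p0 <- mepsc_sim_params(duration = 2, event_rate = 0, seed = 1)
  s0 <- simulate_mepsc_trace(p0)
  expect_identical(nrow(s0$events), 0L)
  # Poisson mean of the truth counts
  counts <- vapply(1:200, function(s) {
    p <- mepsc_sim_params(duration = 120, sampling_rate = 1000,
                          event_rate = 1, seed = s)
    nrow(simulate_mepsc_trace(p)$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 120), 3 * sqrt(120 / 200))
  # noise-free single event reaches -A at the kernel peak
  p1 <- mepsc_sim_params(duration = 3, noise_sd = 0, seed = 1)
  s1 <- simulate_mepsc_trace(p1, event_times = 1, event_amplitudes = 25)
  tpk <- with(p1, rise_tau * decay_tau / (decay_tau - rise_tau) *
                log(decay_tau / rise_tau))
  kmax <- max(mepsc_kernel(seq(0, 5 * tpk, by = 0.1), p1$rise_tau,
                           p1$decay_tau))
  expect_equal(min(s1$trace$current), -25 * kmax, tolerance = 1e-9)
  expect_gt(kmax, 0.99)
})

test_that("c-Fos generator truth matches independent per-blob measurement", {
  # all-qualifying discs
  p <- cfos_image_params(image_shape = c(200, 200), n_cells = 12,
                         radius_range = c(5, 7),
                         eccentricity_range = c(1, 1), seed = 4)
  sim <- simulate_cfos_stack(p)
  expect_identical(sim$n_true, 12L)
  # one blob below the size minimum among 20
  p2 <- cfos_image_params(image_shape = c(256, 256), n_cells = 20,
                          eccentricity_range = c(1, 1), seed = 9)
  radii <- c(rep(6, 19), 2.5)  # area ~ 20 px < 30 px minimum
  sim2 <- simulate_cfos_stack(p2, radii = radii)
  expect_identical(sim2$n_true, 19L)
  expect_false(sim2$truth$qualifies[20])
  expect_lt(sim2$truth$area_px[20], 30)
  # empty image
  expect_identical(simulate_cfos_stack(cfos_image_params(n_cells = 0))$n_true,
                   0L)
})
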
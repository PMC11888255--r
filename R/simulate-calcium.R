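#' Parameters for the synthetic calcium-trace generator
#'
#' Defaults emulate GCaMP6f-like somatic fluorescence: Poisson spiking
#' convolved with a difference-of-exponentials transient (0.1 s rise,
#' 0.6 s decay), a slow sinusoidal baseline drift, and additive Gaussian
#' shot-like noise, sampled at 10 Hz.
#'
#' @param n_units Number of units (cells).
#' @param duration Recording duration, s.
#' @param frame_rate Sampling rate, Hz.
#' @param spike_rate Poisson spike rate per unit, Hz.
#' @param kernel_rise,kernel_decay Transient kernel time constants, s
#'   (`kernel_rise < kernel_decay`).
#' @param transient_amplitude Peak amplitude of a single transient, as a
#'   fraction of baseline (dF/F0 units).
#' @param drift_amplitude Amplitude of the slow baseline drift, fraction of
#'   baseline.
#' @param drift_period Period of the drift sinusoid, s.
#' @param noise_sd Gaussian noise SD, fraction of baseline.
#' @param baseline Baseline fluorescence, arbitrary units.
#' @param group_rate_multiplier Spike-rate multiplier applied when simulating
#'   a stimulated condition (see [simulate_calcium_traceset()]).
#' @param seed Integer seed; generation is bit-reproducible given
#'   `(params, seed)`.
#' @return An object of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(n_units = 20, duration = 120, frame_rate = 10,
                               spike_rate = 1 / 60, kernel_rise = 0.1,
                               kernel_decay = 0.6, transient_amplitude = 0.5,
                               drift_amplitude = 0.05, drift_period = 60,
                               noise_sd = 0.02, baseline = 100,
                               group_rate_multiplier = 2, seed = 1L) {
  p <- list(n_units = check_count(n_units, "n_units"),
            duration = check_positive(duration, "duration"),
            frame_rate = check_positive(frame_rate, "frame_rate"),
            spike_rate = check_positive(spike_rate, "spike_rate",
                                        strict = FALSE),
            kernel_rise = check_positive(kernel_rise, "kernel_rise"),
            kernel_decay = check_positive(kernel_decay, "kernel_decay"),
            transient_amplitude = check_positive(transient_amplitude,
                                                 "transient_amplitude"),
            drift_amplitude = check_positive(drift_amplitude,
                                             "drift_amplitude", strict = FALSE),
            drift_period = check_positive(drift_period, "drift_period"),
            noise_sd = check_positive(noise_sd, "noise_sd", strict = FALSE),
            baseline = check_positive(baseline, "baseline"),
            group_rate_multiplier = check_positive(group_rate_multiplier,
                                                   "group_rate_multiplier"),
            seed = check_count(seed, "seed", min = 0))
  if (p$frame_rate * p$duration < 2) {
    stop_config("duration", "must give at least 2 frames")
  }
  if (p$kernel_rise >= p$kernel_decay) {
    stop_config("kernel_rise", "must be smaller than `kernel_decay`")
  }
  structure(p, class = "calcium_sim_params")
}

#' Difference-of-exponentials calcium transient kernel
#'
#' `exp(-t/decay) - exp(-t/rise)` for `t >= 0`, normalized to unit peak.
#'
#' @param t Times, s (values < 0 map to 0).
#' @param rise,decay Time constants, s.
#' @return Kernel values, peak exactly 1 at
#'   `t = rise * decay / (decay - rise) * log(decay / rise)`.
#' @export
calcium_kernel <- function(t, rise = 0.1, decay = 0.6) {
  stopifnot(rise > 0, decay > rise)
  tpeak <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tpeak / decay) - exp(-tpeak / rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay) - exp(-t[pos] / rise)) / peak
  out
}

#' Simulate a set of calcium fluorescence traces with ground truth
#'
#' Each unit's raw trace is
#' `baseline * (1 + drift sinusoid) + sum of transients + noise`, where
#' transients are unit-peak difference-of-exponentials kernels scaled to
#' `transient_amplitude * baseline` and placed at Poisson spike times. Under
#' `condition = "stimulated"` the spike rate is multiplied by
#' `group_rate_multiplier`. Drift phases are randomized per unit.
#'
#' @param p A [calcium_sim_params()].
#' @param condition `"control"` or `"stimulated"`.
#' @param spike_times Optional list (length `n_units`) of fixed spike-time
#'   vectors overriding Poisson generation, e.g. for worked examples.
#' @param compartment Metadata tag carried on the result (e.g.
#'   `"dentate-blade"` or `"hilus"`).
#' @return A list with `traces` (a `trace_set`: `traces` matrix of
#'   `n_units x n_frames`, `frame_rate`, `time_s`, `units` metadata tibble)
#'   and `spikes` (list of true spike-time vectors).
#' @export
simulate_calcium_traceset <- function(p = calcium_sim_params(),
                                      condition = c("control", "stimulated"),
                                      spike_times = NULL,
                                      compartment = "dentate-blade") {
  stopifnot(inherits(p, "calcium_sim_params"))
  condition <- match.arg(condition)
  set.seed(p$seed + (condition == "stimulated"))
  rate <- p$spike_rate *
    if (condition == "stimulated") p$group_rate_multiplier else 1
  n_frames <- floor(p$duration * p$frame_rate)
  tt <- (seq_len(n_frames) - 1) / p$frame_rate
  traces <- matrix(0, p$n_units, n_frames)
  truth <- vector("list", p$n_units)
  for (u in seq_len(p$n_units)) {
    if (is.null(spike_times)) {
      n_sp <- rpois(1, rate * p$duration)
      sp <- sort(runif(n_sp, 0, p$duration))
    } else {
      sp <- sort(spike_times[[u]])
    }
    truth[[u]] <- sp
    phase <- runif(1, 0, 2 * pi)
    drift <- p$drift_amplitude * sin(2 * pi * tt / p$drift_period + phase)
    sig <- numeric(n_frames)
    for (s in sp) {
      sig <- sig + calcium_kernel(tt - s, p$kernel_rise, p$kernel_decay)
    }
    traces[u, ] <- p$baseline * (1 + drift) +
      p$transient_amplitude * p$baseline * sig +
      rnorm(n_frames, 0, p$noise_sd * p$baseline)
  }
  ts <- structure(
    list(traces = traces, frame_rate = p$frame_rate, time_s = tt,
         units = tibble::tibble(unit_id = seq_len(p$n_units),
                                condition = condition,
                                compartment = compartment)),
    class = "trace_set")
  list(traces = ts, spikes = truth)
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d units x %d frames @ %g Hz\n",
              nrow(x$traces), ncol(x$traces), x$frame_rate))
  invisible(x)
}

#' @export
as_tibble.trace_set <- function(x, ...) {
  tibble::tibble(
    unit_id = rep(x$units$unit_id, each = ncol(x$traces)),
    time_s = rep(x$time_s, times = nrow(x$traces)),
    intensity = as.vector(t(x$traces))
  ) |>
    dplyr::left_join(x$units, by = "unit_id")
}

#' Render a trace set into a synthetic calcium movie
#'
#' Paints each unit's trace onto the pixels of its mask label, producing a
#' `T x H x W` frame stack plus the label mask, for round-trip testing of
#' mask-based trace extraction.
#'
#' @param ts A `trace_set`.
#' @param shape `c(H, W)` of the movie frames.
#' @param cell_radius Radius of each painted cell, px.
#' @return List with `frames` (`T x H x W` array) and `mask`
#'   (`H x W` integer label matrix).
#' @export
render_calcium_movie <- function(ts, shape = c(64, 64), cell_radius = 3) {
  stopifnot(inherits(ts, "trace_set"))
  n_units <- nrow(ts$traces)
  H <- shape[1]; W <- shape[2]
  # place cells on a grid with margins
  ncol_grid <- ceiling(sqrt(n_units))
  nrow_grid <- ceiling(n_units / ncol_grid)
  if ((2 * cell_radius + 2) * max(ncol_grid, nrow_grid) > min(H, W)) {
    abort("frame shape too small for the requested number of units")
  }
  cy <- round(seq(cell_radius + 2, H - cell_radius - 2,
                  length.out = nrow_grid))
  cx <- round(seq(cell_radius + 2, W - cell_radius - 2,
                  length.out = ncol_grid))
  mask <- matrix(0L, H, W)
  for (u in seq_len(n_units)) {
    gy <- cy[(u - 1) %/% ncol_grid + 1]
    gx <- cx[(u - 1) %% ncol_grid + 1]
    for (i in (gy - cell_radius):(gy + cell_radius)) {
      for (j in (gx - cell_radius):(gx + cell_radius)) {
        if ((i - gy)^2 + (j - gx)^2 <= cell_radius^2) mask[i, j] <- u
      }
    }
  }
  n_frames <- ncol(ts$traces)
  frames <- array(0, dim = c(n_frames, H, W))
  idx <- which(mask > 0)
  lab <- mask[idx]
  for (f in seq_len(n_frames)) {
    frame <- matrix(0, H, W)
    frame[idx] <- ts$traces[lab, f]
    frames[f, , ] <- frame
  }
  list(frames = frames, mask = mask)
}
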
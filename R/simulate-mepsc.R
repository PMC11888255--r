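#' Parameters for the synthetic mEPSC current-trace generator
#'
#' Miniature excitatory postsynaptic currents are simulated as a Poisson
#' train of inward (negative) biexponential deflections on a noisy baseline,
#' as recorded in voltage clamp at -70 mV. Amplitudes are log-normal and
#' reported as positive magnitudes.
#'
#' @param duration Recording duration, s.
#' @param sampling_rate Sampling rate, Hz (>= 1 kHz for resolvable kinetics).
#' @param event_rate Poisson event rate, Hz.
#' @param amp_log_mean,amp_log_sd Log-normal amplitude parameters (log pA).
#' @param rise_tau,decay_tau Kernel time constants, ms
#'   (`rise_tau < decay_tau`).
#' @param noise_sd Gaussian baseline noise SD, pA.
#' @param seed Integer seed.
#' @return An object of class `mepsc_sim_params`.
#' @export
mepsc_sim_params <- function(duration = 120, sampling_rate = 10000,
                             event_rate = 1, amp_log_mean = log(20),
                             amp_log_sd = 0.3, rise_tau = 0.5,
                             decay_tau = 5, noise_sd = 4, seed = 1L) {
  p <- list(duration = check_positive(duration, "duration"),
            sampling_rate = check_positive(sampling_rate, "sampling_rate"),
            event_rate = check_positive(event_rate, "event_rate",
                                        strict = FALSE),
            amp_log_mean = amp_log_mean,
            amp_log_sd = check_positive(amp_log_sd, "amp_log_sd",
                                        strict = FALSE),
            rise_tau = check_positive(rise_tau, "rise_tau"),
            decay_tau = check_positive(decay_tau, "decay_tau"),
            noise_sd = check_positive(noise_sd, "noise_sd", strict = FALSE),
            seed = check_count(seed, "seed", min = 0))
  if (p$rise_tau >= p$decay_tau) {
    stop_config("rise_tau", "must be smaller than `decay_tau`")
  }
  structure(p, class = "mepsc_sim_params")
}

#' Unit-peak biexponential synaptic-event kernel
#'
#' @param t_ms Times in ms (values < 0 map to 0).
#' @param rise_tau,decay_tau Time constants, ms.
#' @return Kernel values with peak exactly 1.
#' @export
mepsc_kernel <- function(t_ms, rise_tau = 0.5, decay_tau = 5) {
  stopifnot(rise_tau > 0, decay_tau > rise_tau)
  tpeak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-tpeak / decay_tau) - exp(-tpeak / rise_tau)
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  out[pos] <- (exp(-t_ms[pos] / decay_tau) - exp(-t_ms[pos] / rise_tau)) / peak
  out
}

#' Simulate an mEPSC current trace with ground truth
#'
#' @param p A [mepsc_sim_params()].
#' @param event_times Optional fixed event times (s) overriding Poisson
#'   generation.
#' @param event_amplitudes Optional fixed amplitudes (pA, positive
#'   magnitudes), recycled to the number of events.
#' @param neuron_id,culture_id,group Metadata carried on the trace.
#' @return A list with `trace` (a `current_trace`: `current` in pA,
#'   `sampling_rate`, metadata) and `events` (truth tibble: `time_s`,
#'   `amplitude_pA`).
#' @export
simulate_mepsc_trace <- function(p = mepsc_sim_params(), event_times = NULL,
                                 event_amplitudes = NULL, neuron_id = 1L,
                                 culture_id = 1L, group = "control") {
  stopifnot(inherits(p, "mepsc_sim_params"))
  set.seed(p$seed)
  n <- floor(p$duration * p$sampling_rate)
  if (is.null(event_times)) {
    n_ev <- rpois(1, p$event_rate * p$duration)
    event_times <- sort(runif(n_ev, 0, p$duration))
  } else {
    event_times <- sort(event_times)
  }
  amps <- if (is.null(event_amplitudes)) {
    exp(rnorm(length(event_times), p$amp_log_mean, p$amp_log_sd))
  } else {
    rep_len(event_amplitudes, length(event_times))
  }
  current <- rnorm(n, 0, p$noise_sd)
  dt_ms <- 1000 / p$sampling_rate
  # render each event over a finite support of 12 decay constants
  supp <- ceiling(12 * p$decay_tau / dt_ms)
  for (k in seq_along(event_times)) {
    i0 <- floor(event_times[k] * p$sampling_rate) + 1
    idx <- i0:min(n, i0 + supp)
    t_ms <- (idx - i0) * dt_ms
    current[idx] <- current[idx] -
      amps[k] * mepsc_kernel(t_ms, p$rise_tau, p$decay_tau)
  }
  trace <- structure(
    list(current = current, sampling_rate = p$sampling_rate,
         neuron_id = neuron_id, culture_id = culture_id, group = group),
    class = "current_trace")
  list(trace = trace,
       events = tibble::tibble(time_s = event_times, amplitude_pA = amps))
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %.1f s @ %g kHz (neuron %s, %s)\n",
              length(x$current) / x$sampling_rate, x$sampling_rate / 1000,
              x$neuron_id, x$group))
  invisible(x)
}

#' @export
as_tibble.current_trace <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$current) - 1) / x$sampling_rate,
    current_pA = x$current)
}
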
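#' Stimulation protocol configuration
#'
#' Describes an intermittent theta-burst style magnetic stimulation protocol
#' as nested periodic structure: `n_cycles` duty cycles, each containing
#' `bursts_per_cycle` bursts delivered at `burst_rate` Hz, each burst
#' containing `pulses_per_burst` pulses at `intra_burst_rate` Hz. The default
#' configuration is the iTBS600 protocol: 600 pulses packed as 3-pulse bursts
#' at 50 Hz delivered at 5 Hz, in 20 duty cycles of 2 s stimulation followed
#' by an 8 s pause.
#'
#' @param n_cycles Number of duty cycles (>= 1).
#' @param bursts_per_cycle Bursts per duty cycle (>= 1).
#' @param pulses_per_burst Pulses per burst (>= 1).
#' @param intra_burst_rate Pulse rate within a burst, Hz.
#' @param burst_rate Burst rate within a cycle, Hz; must be lower than
#'   `intra_burst_rate`.
#' @param inter_cycle_gap Pause between the last pulse of a cycle and the
#'   first pulse of the next cycle, seconds (>= 0).
#' @return An object of class `stim_protocol_config`.
#' @examples
#' cfg <- stim_protocol_config()           # iTBS600
#' n_pulses(cfg)                           # 600
#' @export
stim_protocol_config <- function(n_cycles = 20, bursts_per_cycle = 10,
                                 pulses_per_burst = 3, intra_burst_rate = 50,
                                 burst_rate = 5, inter_cycle_gap = 8) {
  n_cycles <- check_count(n_cycles, "n_cycles")
  bursts_per_cycle <- check_count(bursts_per_cycle, "bursts_per_cycle")
  pulses_per_burst <- check_count(pulses_per_burst, "pulses_per_burst")
  check_positive(intra_burst_rate, "intra_burst_rate")
  check_positive(burst_rate, "burst_rate")
  check_positive(inter_cycle_gap, "inter_cycle_gap", strict = FALSE)
  if (intra_burst_rate <= burst_rate) {
    stop_config("intra_burst_rate", "must exceed `burst_rate`")
  }
  # pulses of one burst must fit before the next burst starts, otherwise the
  # train is not strictly increasing
  if ((pulses_per_burst - 1) / intra_burst_rate >= 1 / burst_rate) {
    stop_config("pulses_per_burst",
                "does not fit within one inter-burst interval at these rates")
  }
  structure(
    list(n_cycles = n_cycles, bursts_per_cycle = bursts_per_cycle,
         pulses_per_burst = pulses_per_burst,
         intra_burst_rate = intra_burst_rate, burst_rate = burst_rate,
         inter_cycle_gap = inter_cycle_gap),
    class = "stim_protocol_config"
  )
}

#' @export
print.stim_protocol_config <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol_config> %d pulses: %d cycles x %d bursts x %d pulses\n",
    n_pulses(x), x$n_cycles, x$bursts_per_cycle, x$pulses_per_burst))
  cat(sprintf("  %g Hz within bursts, %g Hz bursts, %g s inter-cycle gap\n",
              x$intra_burst_rate, x$burst_rate, x$inter_cycle_gap))
  invisible(x)
}

#' Total pulse count of a protocol configuration
#' @param cfg A [stim_protocol_config()].
#' @return Integer pulse count.
#' @export
n_pulses <- function(cfg) {
  stopifnot(inherits(cfg, "stim_protocol_config"))
  cfg$n_cycles * cfg$bursts_per_cycle * cfg$pulses_per_burst
}

#' Generate a stimulation pulse train
#'
#' Expands a protocol configuration into the explicit timestamps of every
#' pulse. Time zero is the first pulse; the inter-cycle gap is measured from
#' the last pulse of a cycle to the first pulse of the next, so one duty
#' cycle of the default iTBS600 protocol spans exactly
#' `bursts_per_cycle / burst_rate + inter_cycle_gap` = 10 s.
#'
#' @param cfg A [stim_protocol_config()].
#' @return A `pulse_train`: list with `t` (strictly increasing timestamps in
#'   seconds, first = 0) and `config`.
#' @examples
#' train <- generate_pulse_train(stim_protocol_config())
#' length(train$t)      # 600
#' max(train$t)         # 191.84
#' @export
generate_pulse_train <- function(cfg) {
  if (!inherits(cfg, "stim_protocol_config")) {
    cfg <- do.call(stim_protocol_config, as.list(cfg))
  }
  cycle_period <- cfg$bursts_per_cycle / cfg$burst_rate + cfg$inter_cycle_gap
  k <- rep(seq_len(cfg$n_cycles) - 1,
           each = cfg$bursts_per_cycle * cfg$pulses_per_burst)
  j <- rep(rep(seq_len(cfg$bursts_per_cycle) - 1, each = cfg$pulses_per_burst),
           times = cfg$n_cycles)
  i <- rep(seq_len(cfg$pulses_per_burst) - 1,
           times = cfg$n_cycles * cfg$bursts_per_cycle)
  t <- k * cycle_period + j / cfg$burst_rate + i / cfg$intra_burst_rate
  structure(list(t = t, config = cfg), class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses over %.2f s\n", length(x$t),
              max(x$t)))
  invisible(x)
}

#' @export
as_tibble.pulse_train <- function(x, ...) {
  tibble::tibble(t_s = x$t)
}

#' Segment a pulse train into cycles and bursts
#'
#' Recovers the nested cycle/burst structure of a pulse train from its
#' inter-pulse gaps alone: a gap exceeding `burst_gap` starts a new burst and
#' a gap exceeding `cycle_gap` starts a new cycle. The defaults (0.1 s and
#' 1 s) sit between the iTBS600 intra-burst (0.02 s), inter-burst (0.2 s) and
#' inter-cycle (8 s) spacings.
#'
#' @param train A `pulse_train` from [generate_pulse_train()], or a numeric
#'   vector of timestamps.
#' @param burst_gap,cycle_gap Gap thresholds in seconds;
#'   `0 < burst_gap < cycle_gap`.
#' @return A tibble with one row per pulse: `pulse` (index), `t_s`, `cycle`,
#'   `burst` (within cycle), `pulse_in_burst`. Empty input yields an empty
#'   tibble.
#' @examples
#' seg <- segment_train(generate_pulse_train(stim_protocol_config()))
#' dplyr::n_distinct(seg$cycle)   # 20
#' @export
segment_train <- function(train, burst_gap = 0.1, cycle_gap = 1.0) {
  t <- if (inherits(train, "pulse_train")) train$t else as.numeric(train)
  if (!(burst_gap > 0 && burst_gap < cycle_gap)) {
    abort("need 0 < `burst_gap` < `cycle_gap`")
  }
  if (length(t) == 0) {
    return(tibble::tibble(pulse = integer(), t_s = numeric(),
                          cycle = integer(), burst = integer(),
                          pulse_in_burst = integer()))
  }
  if (any(diff(t) <= 0)) abort("pulse timestamps must be strictly increasing")
  gaps <- c(Inf, diff(t))
  cycle <- cumsum(gaps > cycle_gap)
  burst_global <- cumsum(gaps > burst_gap)
  tibble::tibble(pulse = seq_along(t), t_s = t, cycle = cycle,
                 burst = burst_global) |>
    dplyr::group_by(.data$cycle) |>
    dplyr::mutate(burst = match(.data$burst, unique(.data$burst))) |>
    dplyr::group_by(.data$cycle, .data$burst) |>
    dplyr::mutate(pulse_in_burst = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Tidy a pulse train into its segmented structure
#'
#' @param x A `pulse_train`.
#' @param ... Passed to [segment_train()].
#' @return The tibble returned by [segment_train()].
#' @method tidy pulse_train
#' @export
tidy.pulse_train <- function(x, ...) segment_train(x, ...)

#' Default imaging schedule for time-lapse spine experiments
#'
#' Eleven scan times: daily baseline scans on days 0--4, the day-4 scan
#' taken immediately before stimulation, five hourly scans starting 1 h
#' after stimulation (stimulation is applied 1 h after the day-4 scan), and
#' a final scan 24 h post-stimulation.
#'
#' @return A tibble with columns `label`, `time_h` (hours from the day-0
#'   scan) and `phase` (`"baseline"` or `"post"`); the stimulation time is
#'   attached as attribute `stim_time_h`.
#' @examples
#' nrow(imaging_schedule())   # 11
#' @export
imaging_schedule <- function() {
  sched <- tibble::tibble(
    label = c(paste0("day", 0:4), paste0("post_", 1:5, "h"), "post_24h"),
    time_h = c(0, 24, 48, 72, 96, 98:102, 121),
    phase = c(rep("baseline", 5), rep("post", 6))
  )
  attr(sched, "stim_time_h") <- 97
  sched
}
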
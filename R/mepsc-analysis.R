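#' Construct an event series
#'
#' @param time_s Event times, s (strictly increasing within
#'   `[0, duration_s]`).
#' @param amplitude_pA Event amplitudes, positive magnitudes in pA.
#' @param area_pA_ms Event areas, pA*ms (> 0).
#' @param duration_s Recording duration, s.
#' @param neuron_id,culture_id,group Metadata.
#' @return A tibble of class `event_series` with the recording duration and
#'   metadata attached as attributes.
#' @export
event_series <- function(time_s, amplitude_pA, area_pA_ms, duration_s,
                         neuron_id = NA, culture_id = NA, group = NA) {
  check_positive(duration_s, "duration_s")
  if (length(time_s)) {
    if (is.unsorted(time_s, strictly = TRUE) ||
        any(time_s < 0 | time_s > duration_s)) {
      abort("event times must be strictly increasing within [0, duration]")
    }
    if (any(amplitude_pA <= 0)) abort("amplitudes must be positive")
    if (any(area_pA_ms <= 0)) abort("areas must be positive")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        amplitude_pA = as.numeric(amplitude_pA),
                        area_pA_ms = as.numeric(area_pA_ms))
  structure(out, duration_s = duration_s, neuron_id = neuron_id,
            culture_id = culture_id, group = group,
            class = c("event_series", class(out)))
}

#' Recording duration of an event series
#' @param series An [event_series()].
#' @return Duration in seconds.
#' @export
series_duration <- function(series) {
  d <- attr(series, "duration_s")
  if (is.null(d)) abort("`series` carries no recording duration")
  d
}

#' Detect miniature synaptic events in a current trace
#'
#' Re-implementation of automated mEPSC detection: the trace is detrended
#' with a long rolling-median baseline, lightly smoothed, and negative
#' deflections crossing an amplitude threshold (a multiple of the robust,
#' MAD-based noise SD) are accepted as events if they keep a
#' biexponential-like shape (the trace must still be substantially below
#' baseline shortly after the peak). A refractory window suppresses double
#' counting; the amplitude is measured on the unsmoothed detrended trace and
#' the area is integrated from onset until the trace returns to baseline or
#' `10 * decay_tau`, whichever comes first.
#'
#' @param trace A `current_trace` (see [simulate_mepsc_trace()]) or numeric
#'   vector of currents in pA (then `sampling_rate` must be given).
#' @param sampling_rate Sampling rate in Hz when `trace` is a bare vector.
#' @param threshold_k Amplitude threshold in robust noise SDs.
#' @param refractory_ms Minimum separation between event peaks, ms.
#' @param baseline_window_ms Rolling-median baseline window, ms.
#' @param smooth_ms Boxcar smoothing window for peak finding, ms
#'   (detection only; amplitudes are refined on the unsmoothed trace).
#' @param decay_tau Assumed decay constant for the integration cap, ms.
#' @param shape_check Require the deflection to persist (below a quarter of
#'   the peak) `2 ms` after the peak; rejects single-sample noise spikes.
#' @return An [event_series()].
#' @export
detect_mepsc_events <- function(trace, sampling_rate = NULL, threshold_k = 3,
                                refractory_ms = 5, baseline_window_ms = 200,
                                smooth_ms = 1, decay_tau = 5,
                                shape_check = TRUE) {
  if (inherits(trace, "current_trace")) {
    x <- trace$current
    fs <- trace$sampling_rate
    meta <- trace[c("neuron_id", "culture_id", "group")]
  } else {
    x <- as.numeric(trace)
    fs <- sampling_rate %||% abort("`sampling_rate` required for raw vectors")
    meta <- list(neuron_id = NA, culture_id = NA, group = NA)
  }
  if (fs < 1000) abort("sampling rate below 1 kHz: mEPSC kinetics unresolvable")
  n <- length(x)
  duration <- n / fs
  dt_ms <- 1000 / fs
  # baseline drift removal
  bw <- min(n, max(3, round(baseline_window_ms / dt_ms)))
  if (bw %% 2 == 0) bw <- bw - 1  # odd window: fast running median
  base <- rolling_median(x, bw)
  d <- x - base
  # light smoothing for detection only
  sw <- max(1, round(smooth_ms / dt_ms))
  sm <- if (sw > 1) as.numeric(stats::filter(d, rep(1 / sw, sw),
                                             sides = 2)) else d
  sm[is.na(sm)] <- 0
  noise_sd <- mad(d)
  thr <- threshold_k * noise_sd
  if (thr <= 0) thr <- .Machine$double.eps
  refr <- max(1, round(refractory_ms / dt_ms))
  # candidate events: contiguous runs of the smoothed trace below -thr, with
  # runs separated by less than the refractory window merged (a large
  # event's noisy decay may graze the threshold twice)
  below <- sm < -thr
  rl <- rle(below)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  runs <- cbind(starts[rl$values], ends[rl$values])
  peaks <- integer(0)
  if (nrow(runs)) {
    merged <- runs[1, , drop = FALSE]
    for (r in seq_len(nrow(runs))[-1]) {
      if (runs[r, 1] - merged[nrow(merged), 2] < refr) {
        merged[nrow(merged), 2] <- runs[r, 2]
      } else {
        merged <- rbind(merged, runs[r, ])
      }
    }
    peaks <- vapply(seq_len(nrow(merged)), function(r) {
      i <- merged[r, 1]:merged[r, 2]
      i[which.min(sm[i])]
    }, integer(1))
  }
  if (shape_check && length(peaks)) {
    look <- round(2 / dt_ms)
    ok <- vapply(peaks, function(i) {
      j <- min(n, i + look)
      sm[j] < -0.25 * abs(sm[i]) || d[j] < -0.25 * abs(d[i])
    }, logical(1))
    peaks <- peaks[ok]
  }
  if (!length(peaks)) {
    return(event_series(numeric(0), numeric(0), numeric(0), duration,
                        meta$neuron_id, meta$culture_id, meta$group))
  }
  half <- max(1, round(1 / dt_ms))
  cap <- round(10 * decay_tau / dt_ms)
  res <- purrr::map_dfr(peaks, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    ipk <- lo + which.min(d[lo:hi]) - 1
    amp <- -d[ipk]
    # onset: last non-negative sample before the peak
    on <- ipk
    while (on > 1 && d[on - 1] < 0) on <- on - 1
    # offset: first return to baseline after the peak, capped
    off <- ipk
    lim <- min(n, ipk + cap)
    while (off < lim && d[off + 1] < 0) off <- off + 1
    seg <- -d[on:off]
    area <- pracma::trapz(seq_along(seg) * dt_ms, seg)
    tibble::tibble(idx = ipk, time_s = (ipk - 1) / fs, amplitude_pA = amp,
                   area_pA_ms = area)
  })
  # deduplicate refined peaks that collapsed onto the same sample
  res <- res[!duplicated(res$idx), ]
  res <- res[order(res$time_s), ]
  res <- res[res$amplitude_pA > 0 & res$area_pA_ms > 0, ]
  event_series(res$time_s, res$amplitude_pA, res$area_pA_ms, duration,
               meta$neuron_id, meta$culture_id, meta$group)
}

#' Average normalized event-quantity distributions across neurons
#'
#' Each neuron's events are histogrammed over common `bin_edges` and
#' normalized to sum 1; the per-neuron distributions are then averaged with
#' equal weight, so the result sums to 1 as well. Neurons without events are
#' excluded with a warning.
#'
#' @param series_list List of [event_series()].
#' @param bin_edges Increasing numeric histogram edges; events outside are
#'   clipped into the outer bins.
#' @param quantity `"amplitude"` or `"area"`.
#' @return Tibble with `bin_left`, `bin_right`, `mean_prop`.
#' @export
averaged_event_distribution <- function(series_list, bin_edges,
                                        quantity = c("amplitude", "area")) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "amplitude") "amplitude_pA" else "area_pA_ms"
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  nb <- length(bin_edges) - 1
  probs <- purrr::imap(series_list, function(s, i) {
    v <- s[[col]]
    if (!length(v)) {
      warn(sprintf("neuron %s has no events; excluded from the average", i))
      return(NULL)
    }
    v <- pmin(pmax(v, bin_edges[1]), bin_edges[length(bin_edges)])
    h <- graphics::hist(v, breaks = bin_edges, plot = FALSE)$counts
    h / sum(h)
  })
  probs <- purrr::compact(probs)
  if (!length(probs)) abort("no neuron contributed any event")
  tibble::tibble(bin_left = bin_edges[-length(bin_edges)],
                 bin_right = bin_edges[-1],
                 mean_prop = Reduce(`+`, probs) / length(probs))
}

#' Summated event area scaled to a 2-minute recording
#'
#' Total event area multiplied by `2 / duration_in_minutes`, expressing each
#' neuron's aggregate synaptic charge transfer per standard 2-minute window
#' regardless of the actual recording length.
#'
#' @param series An [event_series()].
#' @return Scaled summated area, pA*ms.
#' @examples
#' s <- event_series(c(1, 2), c(20, 25), c(100, 120), duration_s = 60)
#' summated_area_2min(s)   # (100 + 120) * 2
#' @export
summated_area_2min <- function(series) {
  dur_min <- series_duration(series) / 60
  if (dur_min <= 0) abort("recording duration must be positive")
  sum(series$area_pA_ms) * 2 / dur_min
}

#' Event frequency of a series
#'
#' @param series An [event_series()].
#' @return Events per second (Hz).
#' @export
event_frequency <- function(series) {
  dur <- series_duration(series)
  if (dur <= 0) abort("recording duration must be positive")
  nrow(series) / dur
}
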
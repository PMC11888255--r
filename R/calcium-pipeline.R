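#' Extract per-label mean-intensity traces from a movie
#'
#' For every nonzero label of the mask, averages the intensities of that
#' label's pixels frame by frame, yielding one fluorescence trace per unit.
#'
#' @param frames `T x H x W` intensity array.
#' @param mask `H x W` integer label matrix (0 = background).
#' @param frame_rate Sampling rate, Hz.
#' @param compartment Metadata tag (e.g. `"dentate-blade"`, `"hilus"`).
#' @return A `trace_set` (see [simulate_calcium_traceset()]).
#' @export
extract_label_traces <- function(frames, mask, frame_rate = 10,
                                 compartment = "dentate-blade") {
  stopifnot(length(dim(frames)) == 3)
  if (!all(dim(frames)[2:3] == dim(mask))) {
    abort("mask shape must match the movie frames")
  }
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) abort("mask contains no nonzero labels")
  n_frames <- dim(frames)[1]
  flat <- matrix(frames, nrow = n_frames)  # T x (H*W), column-major pixels
  traces <- matrix(NA_real_, length(labs), n_frames)
  for (i in seq_along(labs)) {
    idx <- which(as.vector(mask) == labs[i])
    traces[i, ] <- if (length(idx) == 1) flat[, idx] else
      rowMeans(flat[, idx, drop = FALSE])
  }
  structure(
    list(traces = traces, frame_rate = frame_rate,
         time_s = (seq_len(n_frames) - 1) / frame_rate,
         units = tibble::tibble(unit_id = labs, condition = NA_character_,
                                compartment = compartment)),
    class = "trace_set")
}

#' Rolling-median detrending of a fluorescence trace
#'
#' The trend is a centered rolling median (window in frames, reflection
#' padding at the edges; see [rolling_median()] for the even-window rule
#' that removes affine trends exactly in the interior); the detrended trace
#' is the residual `trace - trend`.
#'
#' @param trace Numeric fluorescence trace.
#' @param window Rolling window, frames.
#' @return List with `detrended` and `trend`.
#' @export
detrend_rolling_median <- function(trace, window = 20) {
  if (length(trace) <= window) {
    abort(sprintf("trace length (%d) must exceed the window (%d)",
                  length(trace), window))
  }
  trend <- rolling_median(trace, window)
  list(detrended = trace - trend, trend = trend)
}

#' Compute a dF/F0 trace
#'
#' `dF/F0 = (trace - trend) / mean(trend)`: the residual around the rolling
#' baseline, normalized by the robust baseline level F0 (the mean of the
#' trend), making the result invariant to multiplicative gain.
#'
#' @param trace Raw fluorescence trace.
#' @param trend Baseline trend (e.g. from [detrend_rolling_median()]).
#' @param frame_rate Sampling rate, Hz.
#' @param f0 Baseline convention: `"trend_mean"` (default) or
#'   `"trace_mean"`.
#' @return A `dff_trace`: list with `dff`, `frame_rate`, `f0`.
#' @export
compute_dff <- function(trace, trend, frame_rate = 10,
                        f0 = c("trend_mean", "trace_mean")) {
  f0 <- match.arg(f0)
  stopifnot(length(trace) == length(trend))
  F0 <- if (f0 == "trend_mean") mean(trend) else mean(trace)
  if (!is.finite(F0) || F0 <= 0) {
    abort("baseline F0 must be positive to form dF/F0")
  }
  structure(list(dff = (trace - trend) / F0, frame_rate = frame_rate,
                 f0 = F0), class = "dff_trace")
}

#' Full raw-trace to dF/F0 conversion
#'
#' Convenience wrapper chaining [detrend_rolling_median()] and
#' [compute_dff()]. The baseline window is given in seconds and converted to
#' frames (rounded up to an odd count): a rolling baseline must be long
#' relative to the ~1.5 s indicator transient, otherwise the median tracks
#' the transients and absorbs part of their amplitude. The 20 s default
#' corresponds to a 20-frame window at a ~1 Hz acquisition rate.
#'
#' @param trace Raw fluorescence trace.
#' @param frame_rate Sampling rate, Hz.
#' @param window_s Rolling-median baseline window, seconds.
#' @param window Rolling-median window in frames, overriding `window_s` when
#'   given.
#' @param ... Passed to [compute_dff()].
#' @return A `dff_trace`.
#' @export
dff_pipeline <- function(trace, frame_rate = 10, window_s = 20,
                         window = NULL, ...) {
  if (is.null(window)) {
    window <- max(3, round(window_s * frame_rate))
    if (window %% 2 == 0) window <- window + 1
  }
  window <- min(window, length(trace) - 1)
  dt <- detrend_rolling_median(trace, window)
  compute_dff(trace, dt$trend, frame_rate, ...)
}

#' Detect calcium spikes on a dF/F0 trace
#'
#' Spikes are upward crossings of `mean(dff) + k * sd(dff)` separated by at
#' least `min_separation` seconds. The SD is taken over the full trace; a
#' degenerate zero-SD trace yields zero spikes. Because a calcium transient
#' stays suprathreshold for a stretch comparable to the indicator kinetics
#' while single-frame noise excursions do not, a crossing is only accepted
#' when the trace remains above threshold for at least `min_duration`
#' seconds; this suppresses the threshold-crossing false positives that
#' Gaussian frame noise otherwise produces at a fixed rate.
#'
#' @param dff A `dff_trace` or numeric vector (then `frame_rate` is used).
#' @param k Threshold in SD units.
#' @param min_separation Minimum spike separation, s.
#' @param min_duration Minimum suprathreshold duration of an accepted
#'   crossing, s (0 accepts single-frame crossings).
#' @param frame_rate Sampling rate when `dff` is a bare vector, Hz.
#' @return A `spike_result`: list with `spike_frames`, `threshold`,
#'   `rate_per_min`, `n_spikes`, `duration_s`.
#' @export
detect_calcium_spikes <- function(dff, k = 3, min_separation = 1,
                                  min_duration = 0.2, frame_rate = NULL) {
  if (inherits(dff, "dff_trace")) {
    x <- dff$dff
    fs <- dff$frame_rate
  } else {
    x <- as.numeric(dff)
    fs <- frame_rate %||% abort("`frame_rate` required for raw vectors")
  }
  if (length(x) < 10) abort("trace too short for spike detection")
  s <- sd(x)
  thr <- mean(x) + k * s
  duration <- length(x) / fs
  if (s == 0) {
    inform("zero-variance trace: no spikes detectable")
    frames <- integer(0)
  } else {
    up <- which(x[-1] >= thr & x[-length(x)] < thr) + 1L
    need <- max(1L, round(min_duration * fs))
    if (need > 1L) {
      above <- x >= thr
      up <- up[vapply(up, function(i) {
        j <- i + need - 1L
        j <= length(x) && all(above[i:j])
      }, logical(1))]
    }
    min_gap <- max(1L, round(min_separation * fs))
    frames <- integer(0)
    last <- -Inf
    for (i in up) {
      if (i - last >= min_gap) { frames <- c(frames, i); last <- i }
    }
  }
  structure(list(spike_frames = frames, threshold = thr,
                 n_spikes = length(frames), duration_s = duration,
                 rate_per_min = length(frames) / duration * 60),
            class = "spike_result")
}

#' @export
print.spike_result <- function(x, ...) {
  cat(sprintf("<spike_result> %d spikes in %.1f s (%.2f /min), threshold %.4g\n",
              x$n_spikes, x$duration_s, x$rate_per_min, x$threshold))
  invisible(x)
}

#' Area under a dF/F0 trace
#'
#' Trapezoid-rule integral of the signed dF/F0 trace over time, a summary of
#' subthreshold calcium dynamics. Negatives are integrated as-is unless
#' `clip_negative` is set.
#'
#' @param dff A `dff_trace` or numeric vector.
#' @param frame_rate Sampling rate for bare vectors, Hz.
#' @param clip_negative Clip the trace at zero before integrating.
#' @return AUC in dF/F0 * s.
#' @export
trace_auc <- function(dff, frame_rate = NULL, clip_negative = FALSE) {
  if (inherits(dff, "dff_trace")) {
    x <- dff$dff
    fs <- dff$frame_rate
  } else {
    x <- as.numeric(dff)
    fs <- frame_rate %||% abort("`frame_rate` required for raw vectors")
  }
  if (clip_negative) x <- pmax(x, 0)
  pracma::trapz((seq_along(x) - 1) / fs, x)
}

#' Mean pairwise correlation of a set of traces
#'
#' Mean Pearson correlation over the upper triangle of the pairwise
#' correlation matrix of all traces, the per-culture synchronization
#' summary.
#'
#' @param traces A `trace_set` or `units x frames` matrix.
#' @return Mean pairwise correlation (scalar).
#' @export
pairwise_mean_correlation <- function(traces) {
  M <- if (inherits(traces, "trace_set")) traces$traces else as.matrix(traces)
  if (nrow(M) < 2) abort("need at least 2 traces")
  C <- cor(t(M))
  mean(C[upper.tri(C)])
}

#' Welch power spectral density of a dF/F0 trace
#'
#' One-sided power spectral density by the averaged-periodogram method:
#' the mean-removed trace is split into Hann-windowed segments with 50%
#' overlap, per-segment periodograms are normalized by the window power and
#' averaged. The integral of the PSD over frequency approximates the trace
#' variance. The spectral AUC is the trapezoid integral over `band`.
#'
#' @param dff A `dff_trace` or numeric vector.
#' @param frame_rate Sampling rate for bare vectors, Hz.
#' @param segment_length Segment length in samples (clipped to the trace
#'   length).
#' @param band Frequency band `c(lo, hi)` in Hz for the spectral AUC;
#'   `NULL` integrates the full one-sided spectrum.
#' @return List with `spectrum` (tibble `freq_hz`, `psd`) and `auc`.
#' @export
power_spectrum <- function(dff, frame_rate = NULL, segment_length = 256,
                           band = NULL) {
  if (inherits(dff, "dff_trace")) {
    x <- dff$dff
    fs <- dff$frame_rate
  } else {
    x <- as.numeric(dff)
    fs <- frame_rate %||% abort("`frame_rate` required for raw vectors")
  }
  n <- length(x)
  L <- min(segment_length, n)
  step <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  U <- sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    P <- abs(fft(seg))^2 / (fs * U)
    half <- P[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when L is even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    acc <- acc + half * dbl
  }
  psd <- acc / length(starts)
  freq <- (seq_len(nf) - 1) * fs / L
  spec <- tibble::tibble(freq_hz = freq, psd = psd)
  if (is.null(band)) band <- c(0, fs / 2)
  inb <- spec$freq_hz >= band[1] & spec$freq_hz <= band[2]
  auc <- if (sum(inb) >= 2) {
    pracma::trapz(spec$freq_hz[inb], spec$psd[inb])
  } else 0
  list(spectrum = spec, auc = auc)
}

#' Per-unit calcium activity metrics for a trace set
#'
#' Runs the full pipeline (rolling-median detrend, dF/F0, spike detection,
#' trace AUC, spectral AUC) on every unit of a trace set and returns one
#' tidy row per unit.
#'
#' @param ts A `trace_set`.
#' @param window_s Rolling-median baseline window, seconds.
#' @param k Spike threshold, SD units.
#' @param min_separation Minimum spike separation, s.
#' @param band Spectral AUC band, Hz (`NULL` = full).
#' @return Tibble with `unit_id`, `spikes_per_min`, `n_spikes`, `auc`,
#'   `spectral_auc` plus the unit metadata columns.
#' @export
calcium_unit_metrics <- function(ts, window_s = 20, k = 3,
                                 min_separation = 1, band = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  purrr::map_dfr(seq_len(nrow(ts$traces)), function(u) {
    dff <- dff_pipeline(ts$traces[u, ], ts$frame_rate, window_s)
    sp <- detect_calcium_spikes(dff, k = k, min_separation = min_separation)
    ps <- power_spectrum(dff, band = band)
    tibble::tibble(unit_id = ts$units$unit_id[u],
                   spikes_per_min = sp$rate_per_min, n_spikes = sp$n_spikes,
                   auc = trace_auc(dff), spectral_auc = ps$auc)
  }) |>
    dplyr::left_join(ts$units, by = "unit_id")
}
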
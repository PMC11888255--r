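# Internal validation and numeric helpers shared across modules.

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "tbsquant_config_error", field = field)
}

check_positive <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop_config(field, if (strict) "must be a positive finite number"
                else "must be a non-negative finite number")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    stop_config(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

#' Centered rolling median with reflection padding
#'
#' Computes a rolling median aligned to each sample of `x`. Edges are handled
#' by reflecting the series (without repeating the edge sample). For odd
#' window lengths this is the standard centered median filter. For even
#' window lengths the two possible centered placements of the window are
#' averaged, which keeps the filter index-symmetric; in particular the
#' interior of any affine (linear-trend) series is returned unchanged, so
#' detrending with this filter zeroes linear trends exactly away from the
#' edges.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (>= 1, <= `length(x)`).
#' @return Numeric vector of the same length as `x`.
#' @export
rolling_median <- function(x, window) {
  n <- length(x)
  window <- check_count(window, "window")
  if (window > n) abort(sprintf(
    "`window` (%d) exceeds series length (%d)", window, n))
  if (window == 1) return(x)
  p <- if (window %% 2 == 1) (window - 1) / 2 else window / 2
  if (n < p + 1) abort("series too short for reflection padding")
  xpad <- c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
  if (window %% 2 == 1) {
    # running median of the padded series, centered; O(n log k)
    med <- stats::runmed(xpad, window, endrule = "keep")
    med[p + seq_len(n)]
  } else {
    med <- .roll_median_cpp(xpad, window)
    # average the two centered placements: original windows
    # (i - p .. i + p - 1) at med[i] and (i - p + 1 .. i + p) at med[i + 1]
    (med[seq_len(n)] + med[seq_len(n) + 1]) / 2
  }
}

# Greedy matching of detected event times to ground-truth times within a
# tolerance; each truth matched at most once. Returns logical vector over
# detected (matched) plus count of matched truths.
match_event_times <- function(detected, truth, tol) {
  used <- rep(FALSE, length(truth))
  matched <- rep(FALSE, length(detected))
  for (i in seq_along(detected)) {
    if (length(truth) == 0) break
    d <- abs(truth - detected[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      matched[i] <- TRUE
    }
  }
  list(matched = matched, n_truth_matched = sum(used))
}
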
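# Independent oracles used across test files. These re-derive expected
# values by brute force, never by calling the code paths they check.

# Sum the protocol's inter-pulse intervals one by one.
oracle_final_pulse_time <- function(n_cycles, bursts_per_cycle,
                                    pulses_per_burst, intra_rate, burst_rate,
                                    gap) {
  t <- 0
  for (k in seq_len(n_cycles)) {
    for (j in seq_len(bursts_per_cycle)) {
      for (i in seq_len(pulses_per_burst)) {
        if (k == 1 && j == 1 && i == 1) next
        if (i > 1) {
          t <- t + 1 / intra_rate
        } else if (j > 1) {
          t <- t + 1 / burst_rate - (pulses_per_burst - 1) / intra_rate
        } else {
          # one duty cycle spans bursts_per_cycle/burst_rate + gap, so the
          # last pulse of a cycle and the next cycle's first pulse are
          # separated by the unused tail of the final burst slot plus gap
          t <- t + 1 / burst_rate -
            (pulses_per_burst - 1) / intra_rate + gap
        }
      }
    }
  }
  t
}

# Naive rolling median matching the documented window rule.
oracle_rolling_median <- function(x, w) {
  n <- length(x)
  p <- if (w %% 2 == 1) (w - 1) / 2 else w / 2
  xpad <- c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
  at <- function(i, lo, hi) median(xpad[(i + p + lo):(i + p + hi)])
  vapply(seq_len(n), function(i) {
    if (w %% 2 == 1) at(i, -p, p)
    else (at(i, -p, p - 1) + at(i, -p + 1, p)) / 2
  }, numeric(1))
}

# Elementwise mean over all k x k principal submatrices along the diagonal.
oracle_unit_matrix <- function(C, k) {
  n <- nrow(C)
  wins <- lapply(0:(n - k), function(s) C[s + 1:k, s + 1:k])
  acc <- matrix(0, k, k)
  cnt <- matrix(0, k, k)
  for (W in wins) {
    ok <- is.finite(W)
    acc[ok] <- acc[ok] + W[ok]
    cnt <- cnt + ok
  }
  acc / cnt
}

# Exhaustive two-sided Mann-Whitney permutation p, with U computed by direct
# pairwise comparison counting (not rank sums).
oracle_mwu_exact <- function(a, b) {
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  u_obs <- u_of(a, b)
  sets <- utils::combn(length(pooled), n1)
  uall <- apply(sets, 2, function(s) u_of(pooled[s], pooled[-s]))
  list(U = u_obs, p = mean(abs(uall - mu) >= abs(u_obs - mu) - 1e-9))
}

# Greedy time matching for detection precision/recall.
prec_recall <- function(detected, truth, tol = 0.005) {
  m <- tbsquant:::match_event_times(detected, truth, tol)
  c(precision = mean(m$matched), recall = m$n_truth_matched / length(truth))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
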
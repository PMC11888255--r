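#' Parameters for the synthetic spine-trajectory generator
#'
#' Spine sizes are modeled on the log scale, where multiplicative
#' fluctuations and the long right tail of empirical spine-size
#' distributions arise naturally. Each spine follows a mean-reverting walk
#' toward `log_size_mean`; per-step innovations are correlated across the
#' spines of a segment with a correlation that decays with index distance
#' (adjacent spine IDs are physically closer), rescaled so that adjacent
#' spines have correlation `spatial_corr_near` and the most distant pair
#' `spatial_corr_far`. In the stimulated condition the smallest tercile of
#' spines (by day-4 size) is enlarged by a fixed fraction at every
#' post-stimulation scan.
#'
#' @param n_segments Number of dendritic segments.
#' @param spines_per_segment Spines per segment.
#' @param schedule An [imaging_schedule()] tibble (11 labeled scan times).
#' @param log_size_mean,log_size_sd Mean and SD of initial log sizes
#'   (log arbitrary units).
#' @param reversion_rate Mean-reversion rate toward `log_size_mean`, per day.
#' @param fluctuation_sd SD of per-step log-size innovations.
#' @param spatial_corr_near Innovation correlation of adjacent spines.
#' @param spatial_corr_far Innovation correlation of the most distant pair.
#' @param corr_length Index-distance scale of the correlation decay.
#' @param stim_effect_small Fractional enlargement applied to the smallest
#'   day-4 size tercile at post-stimulation scans (stimulated condition).
#' @param seed Integer seed.
#' @return An object of class `spine_sim_params`.
#' @export
spine_sim_params <- function(n_segments = 20, spines_per_segment = 25,
                             schedule = imaging_schedule(),
                             log_size_mean = 0, log_size_sd = 0.5,
                             reversion_rate = 0.3, fluctuation_sd = 0.1,
                             spatial_corr_near = 0.4,
                             spatial_corr_far = -0.15, corr_length = 6,
                             stim_effect_small = 0.3, seed = 1L) {
  p <- list(n_segments = check_count(n_segments, "n_segments"),
            spines_per_segment = check_count(spines_per_segment,
                                             "spines_per_segment", min = 2),
            schedule = schedule,
            log_size_mean = log_size_mean,
            log_size_sd = check_positive(log_size_sd, "log_size_sd",
                                         strict = FALSE),
            reversion_rate = check_positive(reversion_rate, "reversion_rate",
                                            strict = FALSE),
            fluctuation_sd = check_positive(fluctuation_sd, "fluctuation_sd",
                                            strict = FALSE),
            spatial_corr_near = spatial_corr_near,
            spatial_corr_far = spatial_corr_far,
            corr_length = check_positive(corr_length, "corr_length"),
            stim_effect_small = check_positive(stim_effect_small,
                                               "stim_effect_small",
                                               strict = FALSE),
            seed = check_count(seed, "seed", min = 0))
  for (f in c("spatial_corr_near", "spatial_corr_far")) {
    if (abs(p[[f]]) > 1) stop_config(f, "must lie in [-1, 1]")
  }
  if (!is.data.frame(schedule) || nrow(schedule) != 11 ||
      is.unsorted(schedule$time_h, strictly = TRUE)) {
    stop_config("schedule", "must have 11 strictly increasing scan times")
  }
  # innovation correlation matrix must be positive semi-definite
  C <- spine_spatial_correlation(p$spines_per_segment, p$spatial_corr_near,
                                 p$spatial_corr_far, p$corr_length)
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
    stop_config("spatial_corr_near",
                "together with `spatial_corr_far`/`corr_length` yields a non-PSD innovation covariance")
  }
  structure(p, class = "spine_sim_params")
}

#' Distance-dependent innovation correlation matrix
#'
#' Exponential decay `exp(-d / corr_length)` over index distance `d`,
#' affinely rescaled so that correlation is `near` at `d = 1` and `far` at
#' the maximum distance `n - 1`; diagonal 1.
#'
#' @param n Number of spines.
#' @param near,far Target correlations at distance 1 and `n - 1`.
#' @param corr_length Decay scale, index units.
#' @return An `n x n` correlation matrix.
#' @export
spine_spatial_correlation <- function(n, near, far, corr_length) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- exp(-d / corr_length)
  e1 <- exp(-1 / corr_length)
  emax <- exp(-(n - 1) / corr_length)
  C <- far + (near - far) * (e - emax) / (e1 - emax)
  diag(C) <- 1
  C
}

#' Simulate a spine trajectory set with ground truth
#'
#' Generates per-segment spine-size time series over the 11-point imaging
#' schedule. Log sizes follow
#' `l[t+1] = l[t] + reversion_rate * dt_days * (log_size_mean - l[t]) + eps`,
#' with `eps ~ MVN(0, fluctuation_sd^2 * C)` and `C` the distance-dependent
#' correlation of [spine_spatial_correlation()]. Under
#' `condition = "stimulated"`, `log(1 + stim_effect_small)` is added to
#' smallest-tercile spines (day-4 size terciles) at all post-stimulation
#' scans. A per-segment spine density series (spines/µm) with small
#' multiplicative jitter is attached.
#'
#' @param p A [spine_sim_params()].
#' @param condition `"control"` or `"stimulated"`.
#' @return A list with `sizes` (long tibble: `segment_id`, `spine_id`,
#'   `time_label`, `time_h`, `size_au`, `condition`), `density` (tibble:
#'   `segment_id`, `time_label`, `spines_per_um`, `condition`) and `truth`
#'   (tibble: `segment_id`, `spine_id`, `day4_size`, `tercile`,
#'   `condition`).
#' @export
simulate_spine_trajectory_set <- function(p = spine_sim_params(),
                                          condition = c("control",
                                                        "stimulated")) {
  stopifnot(inherits(p, "spine_sim_params"))
  condition <- match.arg(condition)
  set.seed(p$seed + (condition == "stimulated"))
  sched <- p$schedule
  n_t <- nrow(sched)
  n_sp <- p$spines_per_segment
  C <- spine_spatial_correlation(n_sp, p$spatial_corr_near,
                                 p$spatial_corr_far, p$corr_length)
  Sigma <- p$fluctuation_sd^2 * C
  baseline_idx <- which(sched$label == "day4")
  post_idx <- which(sched$phase == "post")
  dt_days <- diff(sched$time_h) / 24
  out <- vector("list", p$n_segments)
  for (s in seq_len(p$n_segments)) {
    L <- matrix(0, n_sp, n_t)
    L[, 1] <- rnorm(n_sp, p$log_size_mean, p$log_size_sd)
    innov <- if (p$fluctuation_sd > 0) {
      MASS::mvrnorm(n_t - 1, mu = rep(0, n_sp), Sigma = Sigma)
    } else {
      matrix(0, n_t - 1, n_sp)
    }
    if (n_t - 1 == 1) innov <- matrix(innov, nrow = 1)
    for (t in 2:n_t) {
      L[, t] <- L[, t - 1] +
        p$reversion_rate * dt_days[t - 1] * (p$log_size_mean - L[, t - 1]) +
        innov[t - 1, ]
    }
    out[[s]] <- L
  }
  # day-4 size terciles over the whole condition's spine population
  day4 <- unlist(lapply(out, function(L) L[, baseline_idx]))
  terc_breaks <- quantile(day4, c(1 / 3, 2 / 3))
  sizes <- purrr::map_dfr(seq_len(p$n_segments), function(s) {
    L <- out[[s]]
    terc <- findInterval(L[, baseline_idx], terc_breaks) + 1L
    if (condition == "stimulated" && p$stim_effect_small > 0) {
      small <- terc == 1L
      L[small, post_idx] <- L[small, post_idx] + log1p(p$stim_effect_small)
    }
    tibble::tibble(
      segment_id = s,
      spine_id = rep(seq_len(n_sp), times = n_t),
      time_label = rep(sched$label, each = n_sp),
      time_h = rep(sched$time_h, each = n_sp),
      size_au = exp(as.vector(L)),
      tercile = rep(terc, times = n_t)
    )
  })
  truth <- sizes |>
    dplyr::filter(.data$time_label == "day4") |>
    dplyr::transmute(.data$segment_id, .data$spine_id,
                     day4_size = .data$size_au, .data$tercile,
                     condition = condition)
  sizes <- dplyr::mutate(dplyr::select(sizes, -"tercile"),
                         condition = condition)
  density <- tidyr::expand_grid(segment_id = seq_len(p$n_segments),
                                time_label = sched$label) |>
    dplyr::mutate(
      spines_per_um = rep(runif(p$n_segments, 0.8, 1.6), each = n_t) *
        exp(rnorm(dplyr::n(), 0, 0.03)),
      condition = condition)
  list(sizes = sizes, density = density, truth = truth)
}
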
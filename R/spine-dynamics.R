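#' Normalize a time series to its day-4 baseline
#'
#' Divides each series (spine size, or segment density) by its own value at
#' the baseline scan, so the baseline entry becomes exactly 1. Series whose
#' baseline is missing, zero or negative are excluded with a warning.
#'
#' @param df Long tibble with a `time_label` column, a value column and
#'   grouping id columns.
#' @param value Name of the value column (string).
#' @param by Character vector of id columns identifying one series.
#' @param baseline_label Scan label used as baseline.
#' @return `df` with an added `<value>_norm` column, excluded series
#'   dropped; the excluded ids are attached as attribute `excluded`.
#' @export
normalize_to_baseline <- function(df, value, by, baseline_label = "day4") {
  stopifnot(value %in% names(df), all(by %in% names(df)),
            "time_label" %in% names(df))
  base <- df |>
    dplyr::filter(.data$time_label == baseline_label) |>
    dplyr::select(dplyr::all_of(by), baseline__ = dplyr::all_of(value))
  out <- dplyr::left_join(df, base, by = by)
  bad <- out |>
    dplyr::filter(is.na(.data$baseline__) | .data$baseline__ <= 0) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(by)))
  if (nrow(bad)) {
    warn(sprintf("%d series excluded: missing or non-positive %s baseline",
                 nrow(bad), baseline_label))
    out <- dplyr::anti_join(out, bad, by = by)
  }
  out[[paste0(value, "_norm")]] <- out[[value]] / out$baseline__
  out <- dplyr::select(out, -"baseline__")
  attr(out, "excluded") <- bad
  out
}

#' Normalize spine sizes to their day-4 baseline
#'
#' @param sizes Long tibble (`segment_id`, `spine_id`, `time_label`,
#'   `size_au`, ...), as produced by [simulate_spine_trajectory_set()].
#' @param baseline_label Baseline scan label.
#' @return `sizes` with a `size_au_norm` column.
#' @export
normalize_spine_sizes <- function(sizes, baseline_label = "day4") {
  normalize_to_baseline(sizes, "size_au", c("segment_id", "spine_id"),
                        baseline_label)
}

#' Normalize spine densities to their day-4 baseline
#'
#' @param density Tibble (`segment_id`, `time_label`, `spines_per_um`, ...).
#' @param baseline_label Baseline scan label.
#' @return `density` with a `spines_per_um_norm` column.
#' @export
normalize_spine_density <- function(density, baseline_label = "day4") {
  normalize_to_baseline(density, "spines_per_um", "segment_id",
                        baseline_label)
}

#' Size-binned normalized spine-size changes
#'
#' For each spine, computes the normalized change
#' `(size(t) - size(day4)) / size(day4)`, then bins spines by their day-4
#' size using right-closed bins (bin labels are the upper edges) and reports
#' the per-bin mean and s.e.m. By default the edges are the day-4 size
#' quintiles, so bins are equally populated.
#'
#' @param sizes Long spine-size tibble.
#' @param t_label Scan label of the comparison time (not the baseline).
#' @param bin_edges Increasing numeric inner+upper edges; `NULL` uses the
#'   day-4 size quantiles at 0.2, 0.4, 0.6, 0.8, 1.
#' @param baseline_label Baseline scan label.
#' @return Tibble with `bin`, `bin_upper`, `n`, `mean_delta`, `sem_delta`;
#'   empty bins are reported with `n = 0`.
#' @export
delta_size_binned <- function(sizes, t_label, bin_edges = NULL,
                              baseline_label = "day4") {
  if (t_label == baseline_label) abort("`t_label` must differ from baseline")
  wide <- sizes |>
    dplyr::filter(.data$time_label %in% c(baseline_label, t_label)) |>
    dplyr::select(dplyr::any_of(c("segment_id", "spine_id", "condition")),
                  "time_label", "size_au") |>
    tidyr::pivot_wider(names_from = "time_label", values_from = "size_au")
  if (!t_label %in% names(wide)) abort(sprintf(
    "scan label `%s` not present in the data", t_label))
  wide <- wide[complete.cases(wide[c(baseline_label, t_label)]), ]
  if (any(wide[[baseline_label]] <= 0)) abort("baseline sizes must be > 0")
  s0 <- wide[[baseline_label]]
  delta <- (wide[[t_label]] - s0) / s0
  if (is.null(bin_edges)) {
    bin_edges <- unname(quantile(s0, c(0.2, 0.4, 0.6, 0.8, 1)))
  }
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  # right-closed bins labeled by their upper edges; values above the last
  # edge are clipped into the top bin
  bin <- findInterval(s0, bin_edges[-length(bin_edges)],
                      left.open = TRUE) + 1L
  bin <- pmin(bin, length(bin_edges))
  tibble::tibble(bin = seq_along(bin_edges), bin_upper = bin_edges) |>
    dplyr::left_join(
      tibble::tibble(bin = bin, delta = delta) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = dplyr::n(), mean_delta = mean(.data$delta),
                         sem_delta = sd(.data$delta) / sqrt(dplyr::n()),
                         .groups = "drop"),
      by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Classify spines as enlarged or shrunk between two scans
#'
#' A spine is `"enlarged"` when its size at `t_label` strictly exceeds its
#' size at `t_ref_label`, otherwise `"shrunk"` (ties count as shrunk, the
#' conservative rule with respect to enlargement claims). Spines missing
#' either scan are excluded with a message.
#'
#' @param sizes Long spine-size tibble.
#' @param t_ref_label Reference scan label.
#' @param t_label Comparison scan label.
#' @return Tibble with `segment_id`, `spine_id`, `size_ref`, `size_t`,
#'   `label`.
#' @export
classify_spines <- function(sizes, t_ref_label = "day4",
                            t_label = "post_24h") {
  wide <- sizes |>
    dplyr::filter(.data$time_label %in% c(t_ref_label, t_label)) |>
    dplyr::select("segment_id", "spine_id", "time_label", "size_au") |>
    tidyr::pivot_wider(names_from = "time_label", values_from = "size_au")
  for (lbl in c(t_ref_label, t_label)) {
    if (!lbl %in% names(wide)) abort(sprintf("scan label `%s` absent", lbl))
  }
  complete <- complete.cases(wide[c(t_ref_label, t_label)])
  if (any(!complete)) {
    inform(sprintf("%d spine(s) excluded: missing a scan", sum(!complete)))
  }
  wide <- wide[complete, ]
  tibble::tibble(
    segment_id = wide$segment_id, spine_id = wide$spine_id,
    size_ref = wide[[t_ref_label]], size_t = wide[[t_label]],
    label = ifelse(wide[[t_label]] > wide[[t_ref_label]],
                   "enlarged", "shrunk"))
}

#' Transition table between early and late enlarged/shrunk labels
#'
#' @param labels_early,labels_late Classification tibbles from
#'   [classify_spines()] at two comparison times; joined on
#'   `(segment_id, spine_id)`.
#' @return Tibble with `from`, `to`, `n` and `prop` (row proportion within
#'   each `from` group); the four `{enlarged, shrunk}^2` cells are always
#'   present.
#' @export
transition_table <- function(labels_early, labels_late) {
  j <- dplyr::inner_join(
    dplyr::select(labels_early, "segment_id", "spine_id", from = "label"),
    dplyr::select(labels_late, "segment_id", "spine_id", to = "label"),
    by = c("segment_id", "spine_id"))
  lv <- c("enlarged", "shrunk")
  tidyr::expand_grid(from = lv, to = lv) |>
    dplyr::left_join(dplyr::count(j, .data$from, .data$to),
                     by = c("from", "to")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$from) |>
    dplyr::mutate(prop = ifelse(sum(.data$n) > 0, .data$n / sum(.data$n),
                                NA_real_)) |>
    dplyr::ungroup()
}

#' Pairwise spine-size correlation matrix of one dendritic segment
#'
#' Pearson (or Spearman) correlation of the raw size time series of every
#' spine pair over the closely monitored 24-hour window (baseline scan, the
#' five hourly post scans and the 24 h scan). Spines with constant series
#' yield undefined correlations, flagged as `NA`.
#'
#' @param sizes Long spine-size tibble.
#' @param segment Segment id to analyze.
#' @param window_labels Scan labels of the correlation window.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `spine_corr` object: the `n x n` correlation matrix with spine
#'   ids as dimnames, plus attributes `segment` and `window_labels`.
#' @export
spine_correlation_matrix <- function(sizes, segment,
                                     window_labels = c("day4",
                                                       paste0("post_", 1:5,
                                                              "h"),
                                                       "post_24h"),
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  seg <- sizes |>
    dplyr::filter(.data$segment_id == segment,
                  .data$time_label %in% window_labels)
  if (!nrow(seg)) abort(sprintf("segment %s has no data in the window",
                                segment))
  if (dplyr::n_distinct(seg$time_label) < 2) {
    abort("need at least 2 scans in the correlation window")
  }
  wide <- seg |>
    dplyr::select("spine_id", "time_label", "size_au") |>
    tidyr::pivot_wider(names_from = "spine_id", values_from = "size_au") |>
    dplyr::arrange(match(.data$time_label, window_labels))
  M <- as.matrix(wide[, -1, drop = FALSE])
  M <- M[, order(as.numeric(colnames(M))), drop = FALSE]
  C <- suppressWarnings(cor(M, use = "pairwise.complete.obs",
                            method = method))
  # constant series produce NaN: flag as NA, keep the unit diagonal
  C[is.nan(C)] <- NA_real_
  diag(C) <- 1
  structure(C, class = c("spine_corr", "matrix"), segment = segment,
            window_labels = window_labels, method = method)
}

#' Diagonal-averaged unit matrix of a correlation matrix
#'
#' Compresses an `n x n` spine-pair correlation matrix into a fixed `k x k`
#' unit matrix by sliding a `k x k` window along the main diagonal (stride
#' 1) and averaging the `n - k + 1` principal submatrices elementwise, which
#' makes segments with different spine counts comparable. Undefined (`NA`)
#' entries are excluded from each cell's mean; per-cell support counts
#' record how many windows contributed.
#'
#' @param corr Correlation matrix (e.g. from [spine_correlation_matrix()]).
#' @param k Unit-matrix side length.
#' @return A `unit_matrix` object: list with `mean` (`k x k`), `support`
#'   (`k x k` contribution counts) and `n_windows`; or `NULL` (with a
#'   warning) when the segment has fewer than `k` spines, which is skipped
#'   rather than padded to avoid fabricating correlations.
#' @export
unit_matrix <- function(corr, k = 15) {
  C <- unclass(corr)
  n <- nrow(C)
  k <- check_count(k, "k")
  if (n < k) {
    warn(sprintf("segment with %d spines < k = %d: skipped", n, k))
    return(NULL)
  }
  acc <- matrix(0, k, k)
  supp <- matrix(0L, k, k)
  for (s in 0:(n - k)) {
    W <- C[s + seq_len(k), s + seq_len(k)]
    ok <- !is.na(W)
    acc[ok] <- acc[ok] + W[ok]
    supp <- supp + ok
  }
  m <- ifelse(supp > 0, acc / supp, NA_real_)
  structure(list(mean = m, support = supp, n_windows = n - k + 1L),
            class = "unit_matrix")
}

#' @export
print.unit_matrix <- function(x, ...) {
  cat(sprintf("<unit_matrix> %d x %d, averaged over %d window(s)\n",
              nrow(x$mean), ncol(x$mean), x$n_windows))
  invisible(x)
}

#' Tidy a unit matrix into long format
#'
#' @param x A `unit_matrix`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `mean`, `support`.
#' @method tidy unit_matrix
#' @export
tidy.unit_matrix <- function(x, ...) {
  k <- nrow(x$mean)
  tibble::tibble(row = rep(seq_len(k), times = k),
                 col = rep(seq_len(k), each = k),
                 mean = as.vector(x$mean),
                 support = as.vector(x$support))
}

#' Elementwise mean of a list of unit matrices
#'
#' @param ums List of `unit_matrix` objects (NULLs dropped).
#' @return A `k x k` matrix of cellwise means over the list (`NA` cells
#'   excluded).
#' @export
unit_matrix_mean <- function(ums) {
  ums <- purrr::compact(ums)
  if (!length(ums)) abort("no unit matrices to average")
  mats <- lapply(ums, `[[`, "mean")
  apply(simplify2array(mats), c(1, 2), mean, na.rm = TRUE)
}

#' Elementwise variance across a list of unit matrices
#'
#' @param ums List of `unit_matrix` objects (NULLs dropped); at least two
#'   are required for a sample variance.
#' @return A `k x k` matrix of cellwise sample variances.
#' @export
unit_matrix_variance <- function(ums) {
  ums <- purrr::compact(ums)
  if (length(ums) < 2) {
    abort("variance across unit matrices requires at least two matrices")
  }
  mats <- lapply(ums, `[[`, "mean")
  apply(simplify2array(mats), c(1, 2), var, na.rm = TRUE)
}
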
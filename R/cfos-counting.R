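#' Maximum projection of the middle planes of a z-stack
#'
#' Projects the `n` planes centered on the stack midpoint by per-pixel
#' maximum, the standard reduction before counting c-Fos-positive nuclei.
#' For even leftovers the window starts at plane `(z - n) %/% 2` (0-based),
#' keeping the choice deterministic and as symmetric as possible.
#'
#' @param stack `z x H x W` array (or `H x W` matrix treated as one plane).
#' @param n Number of middle planes to project.
#' @return `H x W` matrix.
#' @examples
#' st <- array(rep(1:7, each = 4), dim = c(7, 2, 2))
#' max_project_mid_planes(st)[1, 1]  # planes 2..6 -> max 6
#' @export
max_project_mid_planes <- function(stack, n = 5) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1, dim(stack)))
  z <- dim(stack)[1]
  n <- check_count(n, "n")
  if (z < n) {
    abort(sprintf("stack has %d plane(s) but %d were requested", z, n))
  }
  start <- (z - n) %/% 2  # 0-based start of the centered window
  planes <- (start + 1):(start + n)
  apply(stack[planes, , , drop = FALSE], c(2, 3), max)
}

#' 8-connected component labeling of a binary image
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  .label_components_cpp(mask)
}

#' Shape measurements of labeled components
#'
#' Area is the pixel count; the perimeter is the length of the closed outer
#' contour polygon; circularity is `4 * pi * A / P^2`, capped at 1 (the
#' particle-analysis convention, since contour perimeters of small pixelated
#' discs can push the raw ratio above 1).
#'
#' @param labels Integer label matrix from [label_components()].
#' @return Tibble with `label`, `area_px`, `perimeter_px`, `circularity`.
#' @export
measure_components <- function(labels) {
  n <- max(labels)
  if (n == 0) {
    return(tibble::tibble(label = integer(), area_px = numeric(),
                          perimeter_px = numeric(), circularity = numeric()))
  }
  area <- tabulate(labels[labels > 0], nbins = n)
  contours <- EBImage::ocontour(labels)
  per <- vapply(seq_len(n), function(k) {
    oc <- contours[[k]]
    if (is.null(oc) || nrow(oc) < 2) return(0)
    sum(sqrt(rowSums((oc - rbind(oc[-1, , drop = FALSE],
                                 oc[1, , drop = FALSE]))^2)))
  }, numeric(1))
  circ <- ifelse(per > 0, pmin(1, 4 * pi * area / per^2), 1)
  tibble::tibble(label = seq_len(n), area_px = as.numeric(area),
                 perimeter_px = per, circularity = circ)
}

#' Count c-Fos-positive cells in a region of interest
#'
#' Binarizes the image (Otsu's threshold on the masked pixels by default, so
#' counting is invariant to positive rescaling of the intensities), labels
#' 8-connected components inside the ROI, filters them by area and
#' circularity, and returns the surviving count.
#'
#' @param image `H x W` intensity matrix (e.g. from
#'   [max_project_mid_planes()]).
#' @param mask Logical `H x W` ROI mask; `NULL` uses the full frame.
#' @param threshold `"otsu"` or an absolute intensity cutoff.
#' @param size_range Component area filter, px^2.
#' @param circularity_range Circularity (`4*pi*A/P^2`) filter.
#' @param detail If `TRUE`, return the per-component tibble (with a
#'   `kept` column) instead of the count.
#' @return Integer count, or a tibble when `detail = TRUE`.
#' @export
count_positive_cells <- function(image, mask = NULL, threshold = "otsu",
                                 size_range = c(30, 500),
                                 circularity_range = c(0.4, 1),
                                 detail = FALSE) {
  stopifnot(is.matrix(image))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!all(dim(mask) == dim(image))) {
    abort("`mask` shape must match `image`")
  }
  mask <- mask > 0
  if (!any(mask)) abort("`mask` is empty")
  if (identical(threshold, "otsu")) {
    px <- image[mask]
    hi <- max(px)
    if (hi <= 0) {
      thr <- Inf  # blank ROI: nothing can be foreground
    } else {
      thr <- hi * EBImage::otsu(EBImage::Image(matrix(px / hi, ncol = 1)),
                                range = c(0, 1))
    }
  } else {
    thr <- as.numeric(threshold)
  }
  bin <- image > thr & mask
  labels <- label_components(bin)
  shp <- measure_components(labels)
  shp$kept <- shp$area_px >= size_range[1] & shp$area_px <= size_range[2] &
    shp$circularity >= circularity_range[1] &
    shp$circularity <= circularity_range[2]
  if (detail) shp else sum(shp$kept)
}

#' Count cells across a named set of ROI masks
#'
#' @param image `H x W` intensity matrix.
#' @param roi_masks Named list of logical masks (e.g. EC, DG, CA3, CA1).
#' @param ... Passed to [count_positive_cells()].
#' @return Tibble with `region` and `count`.
#' @export
count_cells_by_roi <- function(image, roi_masks, ...) {
  stopifnot(is.list(roi_masks), !is.null(names(roi_masks)))
  purrr::imap_dfr(roi_masks, function(m, nm) {
    tibble::tibble(region = nm,
                   count = count_positive_cells(image, m, ...))
  })
}

#' Normalize cell counts by the batch control mean
#'
#' Within every `(batch, region)` stratum, divides each culture's raw count
#' by the mean raw count of the control cultures of that stratum, so each
#' batch's control group has mean normalized count 1.
#'
#' @param counts Tibble with columns `culture_id`, `batch_id`, `group`,
#'   `region`, `count`.
#' @param control Group label identifying control cultures.
#' @return The input tibble with a `normalized_count` column.
#' @export
normalize_by_control_mean <- function(counts, control = "control") {
  need <- c("culture_id", "batch_id", "group", "region", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) abort(paste0("`counts` lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(counts$count < 0)) abort("counts must be non-negative")
  strata <- counts |>
    dplyr::group_by(.data$batch_id, .data$region) |>
    dplyr::summarise(
      control_mean = mean(.data$count[.data$group == control]),
      .groups = "drop")
  bad <- strata[is.nan(strata$control_mean), ]
  if (nrow(bad)) {
    abort(paste0("no control cultures in stratum(s): ",
                 paste(sprintf("batch %s / %s", bad$batch_id, bad$region),
                       collapse = "; ")))
  }
  if (any(strata$control_mean == 0)) {
    abort("control mean count is zero in at least one (batch, region) stratum")
  }
  counts |>
    dplyr::left_join(strata, by = c("batch_id", "region")) |>
    dplyr::mutate(normalized_count = .data$count / .data$control_mean) |>
    dplyr::select(-"control_mean")
}
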
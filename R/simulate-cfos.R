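#' Parameters for the synthetic c-Fos image-stack generator
#'
#' Generates confocal-like z-stacks in which c-Fos-positive nuclei are
#' rendered as non-overlapping elliptical blobs of controllable size and
#' circularity, plus a paired DAPI-like stack, with per-blob ground truth
#' for the counting pipeline.
#'
#' @param image_shape `c(H, W)` in pixels.
#' @param n_cells Number of blobs.
#' @param radius_range Range of equivalent radii (radius of the equal-area
#'   circle), px.
#' @param eccentricity_range Range of minor/major axis ratios in (0, 1].
#' @param intensity Blob intensity, arbitrary units.
#' @param background_noise_sd Gaussian background noise SD, a.u.
#' @param n_planes Stack depth.
#' @param seed Integer seed.
#' @return An object of class `cfos_image_params`.
#' @export
cfos_image_params <- function(image_shape = c(128, 128), n_cells = 8,
                              radius_range = c(4, 8),
                              eccentricity_range = c(0.6, 1),
                              intensity = 200, background_noise_sd = 0,
                              n_planes = 7, seed = 1L) {
  p <- list(image_shape = image_shape, n_cells = check_count(n_cells,
                                                             "n_cells",
                                                             min = 0),
            radius_range = radius_range,
            eccentricity_range = eccentricity_range,
            intensity = check_positive(intensity, "intensity"),
            background_noise_sd = check_positive(background_noise_sd,
                                                 "background_noise_sd",
                                                 strict = FALSE),
            n_planes = check_count(n_planes, "n_planes"),
            seed = check_count(seed, "seed", min = 0))
  if (length(image_shape) != 2 || any(image_shape < 16)) {
    stop_config("image_shape", "must be c(H, W) with both >= 16")
  }
  if (any(radius_range <= 0) || radius_range[1] > radius_range[2]) {
    stop_config("radius_range", "must be an increasing positive range")
  }
  if (any(eccentricity_range <= 0) || any(eccentricity_range > 1)) {
    stop_config("eccentricity_range", "must lie in (0, 1]")
  }
  structure(p, class = "cfos_image_params")
}

# render one elliptical blob into an H x W matrix of 0/1
render_blob <- function(shape, center, r_equiv, axis_ratio, theta) {
  a <- r_equiv / sqrt(axis_ratio)   # semi-major
  b <- r_equiv * sqrt(axis_ratio)   # semi-minor; area preserved = pi r^2
  H <- shape[1]; W <- shape[2]
  img <- matrix(0, H, W)
  ii <- max(1, floor(center[1] - a - 1)):min(H, ceiling(center[1] + a + 1))
  jj <- max(1, floor(center[2] - a - 1)):min(W, ceiling(center[2] + a + 1))
  for (i in ii) for (j in jj) {
    dx <- i - center[1]; dy <- j - center[2]
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    if ((u / a)^2 + (v / b)^2 <= 1) img[i, j] <- 1
  }
  img
}

#' Simulate a c-Fos/DAPI image stack pair with ground truth
#'
#' Blobs are placed without overlap (bounding circles separated by at least
#' 2 px); each blob spans three consecutive planes centered within the
#' middle-five window of the stack, so a maximum projection of the five
#' middle planes recovers every blob at full intensity. The ground-truth
#' qualifying count is obtained by rendering each blob in isolation,
#' binarizing, and measuring its area and circularity with the same shape
#' measurements used by [count_positive_cells()]; a blob qualifies when both
#' fall inside `size_range` and `circularity_range`.
#'
#' @param p A [cfos_image_params()].
#' @param size_range,circularity_range Filter ranges defining a qualifying
#'   blob (defaults match [count_positive_cells()]).
#' @param radii,axis_ratios,thetas,centers Optional per-blob overrides
#'   (recycled), for constructing worked examples.
#' @return A list with `cfos` and `dapi` (`z x H x W` arrays), `truth`
#'   (per-blob tibble: geometry, measured `area_px`, `circularity`,
#'   `qualifies`) and `n_true` (number of qualifying blobs).
#' @export
simulate_cfos_stack <- function(p = cfos_image_params(),
                                size_range = c(30, 500),
                                circularity_range = c(0.4, 1),
                                radii = NULL, axis_ratios = NULL,
                                thetas = NULL, centers = NULL) {
  stopifnot(inherits(p, "cfos_image_params"))
  set.seed(p$seed)
  H <- p$image_shape[1]; W <- p$image_shape[2]
  n <- p$n_cells
  r <- if (is.null(radii)) runif(n, p$radius_range[1], p$radius_range[2]) else
    rep_len(radii, n)
  q <- if (is.null(axis_ratios)) runif(n, p$eccentricity_range[1],
                                       p$eccentricity_range[2]) else
    rep_len(axis_ratios, n)
  th <- if (is.null(thetas)) runif(n, 0, pi) else rep_len(thetas, n)
  a_max <- r / sqrt(q)  # bounding radius per blob
  if (is.null(centers) && n > 0) {
    centers <- matrix(NA_real_, n, 2)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in 1:2000) {
        cand <- c(runif(1, a_max[k] + 2, H - a_max[k] - 1),
                  runif(1, a_max[k] + 2, W - a_max[k] - 1))
        if (k == 1) { ok <- TRUE } else {
          dd <- sqrt(rowSums((centers[seq_len(k - 1), , drop = FALSE] -
                                matrix(cand, k - 1, 2, byrow = TRUE))^2))
          ok <- all(dd > a_max[k] + a_max[seq_len(k - 1)] + 2)
        }
        if (ok) { centers[k, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) abort(
        "could not place blobs without overlap; reduce `n_cells` or radii",
        class = "tbsquant_placement_error")
    }
  } else if (n > 0) {
    centers <- matrix(unlist(centers), ncol = 2, byrow = is.list(centers))
  }
  # per-blob truth measured on the blob rendered in isolation
  empty_truth <- tibble::tibble(
    cell = integer(), center_y = numeric(), center_x = numeric(),
    r_equiv = numeric(), axis_ratio = numeric(), theta = numeric(),
    area_px = numeric(), circularity = numeric(), qualifies = logical())
  truth <- purrr::map_dfr(seq_len(n), function(k) {
    bin <- render_blob(c(H, W), centers[k, ], r[k], q[k], th[k])
    shp <- measure_components(label_components(bin > 0.5))
    tibble::tibble(cell = k, center_y = centers[k, 1],
                   center_x = centers[k, 2], r_equiv = r[k],
                   axis_ratio = q[k], theta = th[k],
                   area_px = shp$area_px[1], circularity = shp$circularity[1],
                   qualifies = shp$area_px[1] >= size_range[1] &
                     shp$area_px[1] <= size_range[2] &
                     shp$circularity[1] >= circularity_range[1] &
                     shp$circularity[1] <= circularity_range[2])
  })
  if (n == 0) truth <- empty_truth
  # render the stacks: blob k occupies 3 consecutive planes centered inside
  # the middle-five window
  mid0 <- (p$n_planes - min(5L, p$n_planes)) %/% 2  # 0-based window start
  cfos <- array(rnorm(p$n_planes * H * W, 0, p$background_noise_sd),
                dim = c(p$n_planes, H, W))
  dapi <- array(rnorm(p$n_planes * H * W, 0, p$background_noise_sd),
                dim = c(p$n_planes, H, W))
  wmin <- mid0 + 1
  wmax <- mid0 + min(5L, p$n_planes)
  for (k in seq_len(n)) {
    bin <- render_blob(c(H, W), centers[k, ], r[k], q[k], th[k])
    zc <- if (wmax - wmin >= 2) wmin + 1 + (k - 1) %% (wmax - wmin - 1)
          else wmin
    zz <- max(wmin, zc - 1):min(wmax, zc + 1)
    for (z in zz) {
      cfos[z, , ] <- cfos[z, , ] + p$intensity * bin
      dapi[z, , ] <- dapi[z, , ] + 0.6 * p$intensity *
        render_blob(c(H, W), centers[k, ], r[k] * 0.8, q[k], th[k])
    }
  }
  list(cfos = cfos, dapi = dapi, truth = truth,
       n_true = sum(truth$qualifies))
}
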
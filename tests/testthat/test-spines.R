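make_sizes <- function(mat, labels = imaging_schedule()$label,
                       segment_id = 1L) {
  # mat: spines x time points
  tibble::tibble(
    segment_id = segment_id,
    spine_id = rep(seq_len(nrow(mat)), times = ncol(mat)),
    time_label = rep(labels[seq_len(ncol(mat))], each = nrow(mat)),
    time_h = rep(seq_len(ncol(mat)), each = nrow(mat)),
    size_au = as.vector(mat))
}

test_that("baseline normalization divides each series by its day-4 value", {
  sim <- simulate_spine_trajectory_set(spine_sim_params(n_segments = 3,
                                                        seed = 4))
  norm <- normalize_spine_sizes(sim$sizes)
  at_base <- norm$size_au_norm[norm$time_label == "day4"]
  expect_true(all(at_base == 1))
  # (2, 4) with baseline 2 -> (1, 2)
  toy <- tibble::tibble(segment_id = 1L, spine_id = 1L,
                        time_label = c("day4", "post_24h"),
                        size_au = c(2, 4))
  out <- normalize_spine_sizes(toy)
  expect_equal(out$size_au_norm, c(1, 2))
  # constant trajectory normalizes to all ones
  const <- tibble::tibble(segment_id = 1L, spine_id = 1L,
                          time_label = c("day4", "post_1h", "post_24h"),
                          size_au = c(3, 3, 3))
  expect_true(all(normalize_spine_sizes(const)$size_au_norm == 1))
  # zero baseline excluded with a warning
  bad <- dplyr::bind_rows(toy, tibble::tibble(
    segment_id = 1L, spine_id = 2L, time_label = c("day4", "post_24h"),
    size_au = c(0, 1)))
  expect_warning(out2 <- normalize_spine_sizes(bad), "excluded")
  expect_false(2L %in% out2$spine_id)
  expect_identical(nrow(attr(out2, "excluded")), 1L)
})

test_that("density normalization anchors day 4 at one", {
  sim <- simulate_spine_trajectory_set(spine_sim_params(n_segments = 4,
                                                        seed = 6))
  nd <- normalize_spine_density(sim$density)
  expect_true(all(nd$spines_per_um_norm[nd$time_label == "day4"] == 1))
})

test_that("binned size changes report zero for unchanged spines", {
  mat <- matrix(rep(runif(12, 0.5, 2), 11), nrow = 12)
  sizes <- make_sizes(mat)
  b <- delta_size_binned(sizes, "post_24h")
  expect_true(all(b$mean_delta[b$n > 0] == 0))
  # a single spine occupies exactly one bin
  single <- make_sizes(matrix(rep(1, 11), nrow = 1))
  b1 <- delta_size_binned(single, "post_24h", bin_edges = c(0.5, 1, 2))
  expect_identical(sum(b1$n > 0), 1L)
  expect_identical(b1$n[b1$bin_upper == 1], 1L)   # right-closed: 1 in (0.5,1]
  expect_identical(sum(b1$n), 1L)
})

test_that("binned size changes recover size-dependent drift", {
  sim <- simulate_spine_trajectory_set(spine_sim_params(n_segments = 100,
                                                        seed = 30))
  b <- delta_size_binned(sim$sizes, "post_24h")
  expect_gt(b$mean_delta[1], b$mean_delta[nrow(b)])
  expect_gt(b$mean_delta[1], 0)
  expect_lt(b$mean_delta[nrow(b)], 0)
})

test_that("classification is strict-enlargement with ties shrunk", {
  mat <- rbind(c(1.0, 1.2), c(1.0, 1.0), c(1.0, 0.8))
  sizes <- make_sizes(mat, labels = c("day4", "post_24h"))
  lab <- classify_spines(sizes)
  expect_identical(lab$label, c("enlarged", "shrunk", "shrunk"))
  # missing scans excluded with a message
  holey <- sizes[-2, ]
  expect_message(lab2 <- classify_spines(holey), "excluded")
  expect_identical(nrow(lab2), 2L)
})

test_that("stimulated smallest-tercile spines are mostly enlarged", {
  p <- spine_sim_params(n_segments = 40, stim_effect_small = 0.5, seed = 44)
  sim <- simulate_spine_trajectory_set(p, "stimulated")
  lab <- classify_spines(sim$sizes)
  lab <- dplyr::inner_join(lab, sim$truth, by = c("segment_id", "spine_id"))
  small <- dplyr::filter(lab, tercile == 1L)
  expect_gt(mean(small$label == "enlarged"), 0.5)
})

test_that("transition tables count co-observed spines exactly", {
  # hand fixture: 6 spines with known early/late paths
  early <- tibble::tibble(segment_id = 1L, spine_id = 1:6,
                          label = c("enlarged", "enlarged", "shrunk",
                                    "shrunk", "shrunk", "enlarged"))
  late <- tibble::tibble(segment_id = 1L, spine_id = 1:6,
                         label = c("enlarged", "shrunk", "enlarged",
                                   "enlarged", "shrunk", "enlarged"))
  tt <- transition_table(early, late)
  expect_identical(sum(tt$n), 6L)
  cell <- function(f, t) tt$n[tt$from == f & tt$to == t]
  expect_identical(cell("enlarged", "enlarged"), 2L)
  expect_identical(cell("enlarged", "shrunk"), 1L)
  expect_identical(cell("shrunk", "enlarged"), 2L)
  expect_identical(cell("shrunk", "shrunk"), 1L)
  expect_equal(tt$prop[tt$from == "shrunk" & tt$to == "enlarged"], 2 / 3)
  # all spines on one path: a single nonzero cell
  tt1 <- transition_table(dplyr::mutate(early, label = "shrunk"),
                          dplyr::mutate(late, label = "enlarged"))
  expect_identical(sum(tt1$n > 0), 1L)
})

test_that("correlation matrices match hand-computed Pearson values", {
  w <- c(1, 2, 4, 3, 5, 4, 6)           # 7 scans in the 24 h window
  mat <- rbind(w, w + 1, 10 - w)        # identical, shifted, negated
  sizes <- make_sizes(mat, labels = c("day4", paste0("post_", 1:5, "h"),
                                      "post_24h"))
  C <- spine_correlation_matrix(sizes, 1)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(unclass(C), t(unclass(C)), ignore_attr = TRUE)
  # hand fixture vs cor()
  set.seed(1)
  m3 <- matrix(rnorm(21), nrow = 3)
  s3 <- make_sizes(m3, labels = c("day4", paste0("post_", 1:5, "h"),
                                  "post_24h"))
  C3 <- spine_correlation_matrix(s3, 1)
  expect_equal(C3[1, 2], cor(m3[1, ], m3[2, ]))
  expect_equal(C3[2, 3], cor(m3[2, ], m3[3, ]))
  # constant trajectories flag undefined correlations
  m4 <- rbind(w, rep(2, 7))
  C4 <- spine_correlation_matrix(make_sizes(
    m4, labels = c("day4", paste0("post_", 1:5, "h"), "post_24h")), 1)
  expect_true(is.na(C4[1, 2]))
  expect_identical(C4[2, 2], 1)
})

test_that("unit matrices average sliding diagonal windows", {
  # n = k: the unit matrix is the input
  set.seed(7)
  A <- cor(matrix(rnorm(15 * 40), ncol = 15))
  u <- unit_matrix(A, k = 15)
  expect_equal(u$mean, A, ignore_attr = TRUE)
  expect_true(all(u$support == 1))
  # constant off-diagonal: all 26 windows identical
  n <- 40; c0 <- 0.3
  B <- matrix(c0, n, n); diag(B) <- 1
  ub <- unit_matrix(B, k = 15)
  expect_equal(ub$mean, oracle_unit_matrix(B, 15), tolerance = 1e-14)
  expect_true(all(abs(ub$mean[upper.tri(ub$mean)] - c0) < 1e-14))
  expect_true(all(diag(ub$mean) == 1))
  expect_identical(ub$n_windows, 26L)
  # symmetry is preserved and side length is 15 by default
  expect_equal(ub$mean, t(ub$mean))
  expect_identical(dim(ub$mean), c(15L, 15L))
  # too-small segments are skipped with a warning, not padded
  expect_warning(expect_null(unit_matrix(B[1:10, 1:10], k = 15)), "skipped")
})

test_that("unit matrices handle undefined entries via support counts", {
  A <- matrix(0.5, 20, 20); diag(A) <- 1
  A[1, 20] <- A[20, 1] <- NA
  u <- unit_matrix(A, k = 15)
  expect_true(all(u$support <= 6))
  expect_false(anyNA(u$mean))
  expect_equal(u$mean, oracle_unit_matrix(A, 15), tolerance = 1e-14)
})

test_that("unit-matrix summaries commute with relabeling and vary correctly", {
  set.seed(9)
  ums <- lapply(1:4, function(i) unit_matrix(cor(matrix(rnorm(18 * 30),
                                                        ncol = 18)), 15))
  perm <- c(3, 1, 4, 2)
  expect_equal(unit_matrix_mean(ums), unit_matrix_mean(ums[perm]))
  expect_equal(unit_matrix_variance(ums), unit_matrix_variance(ums[perm]))
  # identical matrices: zero variance map
  expect_true(all(unit_matrix_variance(list(ums[[1]], ums[[1]])) == 0))
  # two matrices: elementwise sample variance by hand
  v <- unit_matrix_variance(ums[1:2])
  expect_equal(v[2, 3],
               var(c(ums[[1]]$mean[2, 3], ums[[2]]$mean[2, 3])))
  expect_error(unit_matrix_variance(ums[1]), "at least two")
})
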
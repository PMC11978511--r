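# double-loop moment oracle for the first six Hu invariants
oracle_hu6 <- function(patch) {
  m <- function(p, q) {
    s <- 0
    for (i in seq_len(nrow(patch))) for (j in seq_len(ncol(patch)))
      s <- s + (i - 1)^p * (j - 1)^q * patch[i, j]
    s
  }
  m00 <- m(0, 0); cy <- m(1, 0) / m00; cx <- m(0, 1) / m00
  mu <- function(p, q) {
    s <- 0
    for (i in seq_len(nrow(patch))) for (j in seq_len(ncol(patch)))
      s <- s + (i - 1 - cy)^p * (j - 1 - cx)^q * patch[i, j]
    s
  }
  e <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  e20 <- e(2, 0); e02 <- e(0, 2); e11 <- e(1, 1)
  e30 <- e(3, 0); e03 <- e(0, 3); e21 <- e(2, 1); e12 <- e(1, 2)
  c(e20 + e02,
    (e20 - e02)^2 + 4 * e11^2,
    (e30 - 3 * e12)^2 + (3 * e21 - e03)^2,
    (e30 + e12)^2 + (e21 + e03)^2,
    (e30 - 3 * e12) * (e30 + e12) * ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
      (3 * e21 - e03) * (e21 + e03) * (3 * (e30 + e12)^2 - (e21 + e03)^2),
    (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
      4 * e11 * (e30 + e12) * (e21 + e03))
}

hu_impl <- function(patch) organellometry:::hu6(patch)

test_that("Hu invariants match a double-loop oracle and are invariant", {
  set.seed(11)
  patch <- matrix(runif(15 * 15), 15, 15)
  expect_equal(hu_impl(patch), oracle_hu6(patch), tolerance = 1e-12)
  # translation: embed the same patch at two offsets of a larger canvas
  big1 <- matrix(0, 31, 31); big1[3:17, 4:18] <- patch
  big2 <- matrix(0, 31, 31); big2[11:25, 13:27] <- patch
  expect_equal(hu_impl(big1), hu_impl(big2), tolerance = 1e-12)
  # 90-degree rotation is an exact pixel permutation
  rot90 <- t(patch)[ncol(patch):1, ]
  expect_lt(max(abs(hu_impl(patch) - hu_impl(rot90))), 1e-9)
})

test_that("stored Hu invariants survive rotation and rescale of a smooth blob", {
  # asymmetric smooth blob: the odd-order invariants must be robustly
  # nonzero, otherwise their log-magnitudes are undefined noise
  render_blob <- function(n, cy, cx, s, theta) {
    yy <- outer(seq_len(n) - cy, rep(1, n)); xx <- t(outer(seq_len(n) - cx, rep(1, n)))
    yr <- cos(theta) * yy + sin(theta) * xx
    xr <- -sin(theta) * yy + cos(theta) * xx
    exp(-(yr^2 / (2 * (2 * s)^2) + xr^2 / (2 * s^2))) +
      0.6 * exp(-((yr - 1.5 * s)^2 + (xr - s)^2) / (2 * s^2))
  }
  a <- render_blob(81, 41, 41, 4, 0)
  b <- render_blob(81, 41, 41, 4 * 1.1, 0.63)  # rotated + 10% rescale
  ha <- organellometry:::signed_log10(hu_impl(a))
  hb <- organellometry:::signed_log10(hu_impl(b))
  expect_lt(max(abs(ha - hb)), 1e-2)
})

test_that("markers sit at distance-transform peaks, one per organelle", {
  s <- shape_sphere(15, 5)
  h <- hierarchy_from_mask(s, spacing = c(1, 1, 1))
  mk <- detect_markers(h)
  expect_equal(nrow(mk), 1L)
  expect_true(all(abs(c(mk$zi, mk$yi, mk$xi) - 7) <= 1))
  expect_equal(mk$radius_um, max(h$distance_um), tolerance = 1e-9)

  # empty mask: no markers
  he <- suppressWarnings(hierarchy_from_mask(array(FALSE, c(1, 8, 8))))
  expect_equal(nrow(detect_markers(he)), 0L)

  # two well-separated spheres: one marker each
  m2 <- array(FALSE, c(1, 40, 21))
  m2[1, 4:16, 5:17][shape_disc(13, 5)[1, , ]] <- TRUE
  m2[1, 24:36, 5:17][shape_disc(13, 5)[1, , ]] <- TRUE
  h2 <- hierarchy_from_mask(m2)
  mk2 <- detect_markers(h2)
  expect_equal(nrow(mk2), 2L)
  expect_equal(sort(unique(h2$organelle_labels[cbind(1, mk2$yi + 1, mk2$xi + 1)])),
               c(1L, 2L))
})

test_that("marker features: stats of uniform patches, Hu vector lengths", {
  s <- shape_disc(21, 6)
  h <- hierarchy_from_mask(s)
  raw <- array(7, dim(s))
  mk <- marker_feature_vectors(detect_markers(h), raw, raw * 2, c(1, 1))
  expect_equal(ncol(mk$hu_vec), 12L)
  expect_equal(mk$stats_vec[1, 1], 7)
  expect_equal(mk$stats_vec[1, 2], 0)
  expect_equal(mk$stats_vec[1, 3], 14)
  s3 <- shape_sphere(15, 5)
  h3 <- hierarchy_from_mask(s3, spacing = c(1, 1, 1))
  raw3 <- array(1, dim(s3))
  mk3 <- marker_feature_vectors(detect_markers(h3), raw3, raw3, c(1, 1, 1))
  expect_equal(ncol(mk3$hu_vec), 36L)
  expect_true(all(is.finite(mk3$hu_vec)))
})

test_that("cost matrix: z-scored blocks, admissibility, diagonal optimality", {
  set.seed(3)
  mk <- data.frame(marker_id = 1:5, z = 0, y = c(2, 9, 16, 23, 30),
                   x = c(3, 11, 5, 17, 25), zi = 0L,
                   yi = c(2, 9, 16, 23, 30), xi = c(3, 11, 5, 17, 25),
                   radius_um = 1.5)
  mk$stats_vec <- matrix(rnorm(20), 5)
  mk$hu_vec <- matrix(rnorm(60), 5)
  cm <- build_cost_matrix(mk, mk, spacing = c(1, 1), max_travel_um = 12)
  # identical sets: diagonal entries are row and column minima
  for (i in 1:5) {
    expect_equal(which.min(cm$cost[i, ]), i)
    expect_equal(which.min(cm$cost[, i]), i)
  }
  # admissibility masks pairs farther than max_travel
  expect_false(cm$admissible[1, 5])
  expect_true(is.infinite(cm$cost[1, 5]))
  # each z-scored block has mean ~0 over admissible entries by construction
  zd <- organellometry:::zscore_over(
    sqrt(outer(mk$y, mk$y, `-`)^2 + outer(mk$x, mk$x, `-`)^2), cm$admissible)
  expect_equal(mean(zd[cm$admissible]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(zd[cm$admissible]), 1, tolerance = 1e-12)
})

test_that("best-match linking allows n-to-1 and swaps with frame order", {
  set.seed(5)
  mk_a <- data.frame(marker_id = 1:2, z = 0, y = c(5, 8), x = c(5, 5),
                     zi = 0L, yi = c(5, 8), xi = c(5, 5), radius_um = 1)
  mk_a$stats_vec <- matrix(rnorm(8), 2); mk_a$hu_vec <- matrix(rnorm(24), 2)
  mk_b <- mk_a[1, , drop = FALSE]       # one admissible target
  cm <- build_cost_matrix(mk_a, mk_b, c(1, 1), max_travel_um = 5)
  lk <- link_best_match(cm)
  expect_equal(nrow(lk$forward$links), 2L)       # 2-to-1 forward
  expect_equal(lk$forward$links$target, c(1, 1))
  expect_equal(nrow(lk$backward$links), 1L)
  expect_equal(lk$backward$links$target,
               which.min(cm$cost[, 1]))
  # symmetry: swapping the frames swaps forward/backward exactly
  cm_r <- build_cost_matrix(mk_b, mk_a, c(1, 1), max_travel_um = 5)
  lk_r <- link_best_match(cm_r)
  expect_equal(lk_r$forward$links$target, lk$backward$links$target)
  expect_equal(lk_r$forward$links$cost, lk$backward$links$cost)
  expect_equal(lk_r$forward$links$dx, lk$backward$links$dx)
})

test_that("appearance breaks ties that distance alone cannot", {
  # two markers swap neighbourhoods; distances tie by symmetry, so the
  # stats/Hu blocks must decide, and they follow appearance
  mk_t <- data.frame(marker_id = 1:2, z = 0, y = c(10, 14), x = c(10, 10),
                     zi = 0L, yi = c(10, 14), xi = c(10, 10), radius_um = 1)
  mk_t$stats_vec <- rbind(c(10, 1, 5, 1), c(50, 2, 9, 2))
  mk_t$hu_vec <- rbind(rep(-1, 12), rep(-3, 12))
  mk_s <- mk_t
  mk_s$y <- c(14, 10)                      # swapped positions, same features
  cm <- build_cost_matrix(mk_t, mk_s, c(1, 1), max_travel_um = 10)
  lk <- link_best_match(cm)
  expect_equal(lk$forward$links$target, c(1, 2))  # follows appearance
})

test_that("markers and links ignore organelle label permutations", {
  spec <- scene_blob_field(speed_vox = 0.5, seed = 9, n_frames = 2)
  st <- render_timelapse(build_scene(spec))
  res <- run_pipeline(st, pipeline_config())
  h1 <- res$hierarchies[[1]]
  # permute organelle labels and recompute markers
  perm <- sample(max(h1$organelle_labels))
  h1p <- h1
  h1p$organelle_labels[h1$semantic] <- perm[h1$organelle_labels[h1$semantic]]
  raw1 <- array(st$data[1, , , ], dim(h1$semantic))
  mk <- detect_markers(h1, raw1)
  mkp <- detect_markers(h1p, raw1)
  expect_equal(mk[, c("z", "y", "x", "radius_um")],
               mkp[, c("z", "y", "x", "radius_um")])
})
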
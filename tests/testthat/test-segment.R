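# independent histogram-threshold oracle: plain double loops over 256 bins
oracle_otsu <- function(v) {
  edges <- seq(min(v), max(v), length.out = 257)
  cnt <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), 256), 256)
  mids <- (edges[-1] + edges[-257]) / 2
  best <- -Inf; bk <- 1
  for (k in 1:255) {
    w0 <- sum(cnt[1:k]); w1 <- sum(cnt) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(cnt[1:k] * mids[1:k]) / w0
    m1 <- sum(cnt[(k + 1):256] * mids[(k + 1):256]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best + 1e-15) { best <- bc; bk <- k }
  }
  edges[bk + 1]
}
oracle_triangle <- function(v) {
  edges <- seq(min(v), max(v), length.out = 257)
  cnt <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), 256), 256)
  p <- which.max(cnt)
  nz <- which(cnt > 0); lo <- nz[1]; hi <- nz[length(nz)]
  b <- if ((hi - p) >= (p - lo)) hi else lo
  if (p == b) return((edges[p] + edges[p + 1]) / 2)
  ks <- if (b > p) p:b else b:p
  dxl <- b - p; dyl <- cnt[b] - cnt[p]
  dist <- abs(dyl * (ks - p) - dxl * (cnt[ks] - cnt[p])) / sqrt(dxl^2 + dyl^2)
  edges[ks[which.max(dist)] + 1]
}

test_that("minotri equals min(Otsu, triangle) from an independent oracle", {
  set.seed(4)
  # right-skewed unimodal: lognormal-ish values
  v <- c(rlnorm(3000, -2, 0.5), rlnorm(300, 0, 0.3))
  resp <- array(0, c(1, 1, length(v) + 10)); resp[1, 1, 1:length(v)] <- v
  expect_equal(minotri_threshold(resp), min(oracle_otsu(v), oracle_triangle(v)),
               tolerance = 1e-12)
  # bimodal: threshold strictly between the modes
  v2 <- c(rnorm(2000, 0.1, 0.01), rnorm(2000, 0.9, 0.01))
  resp2 <- array(0, c(1, 1, length(v2))); resp2[] <- v2
  thr <- minotri_threshold(resp2)
  expect_gt(thr, 0.11); expect_lt(thr, 0.89)
  expect_error(minotri_threshold(array(1, c(1, 2, 2))), "distinct")
  expect_error(otsu_threshold(array(0, c(1, 2, 2))), "distinct")
})

test_that("semantic mask drops specks and warns on empty masks", {
  resp <- array(0, c(1, 20, 20))
  resp[1, 3, 3] <- 1; resp[1, 18, 18] <- 1        # two 1-voxel specks
  resp[1, 5:14, 5:14] <- 1                        # 100-voxel object
  m <- semantic_mask(resp, 0.5, 0, spacing = c(1, 1))
  lab <- label_organelles(m)
  expect_equal(max(lab), 1L)
  expect_equal(sum(m), 100)
  expect_warning(semantic_mask(resp, 2, 0, spacing = c(1, 1)), "empty")
  # min-size in physical units
  expect_warning(
    m2 <- semantic_mask(resp, 0.5, min_size_um = 150, spacing = c(1, 1)),
    "empty")
  expect_equal(sum(m2), 0)
})

test_that("organelle labeling uses full connectivity in scan order", {
  m <- array(FALSE, c(5, 9, 9))
  m[2:3, 2:3, 2:3] <- TRUE
  m[4, 4, 4] <- TRUE                 # touches only at a corner: same label
  lab <- label_organelles(m)
  expect_equal(max(lab), 1L)
  m2 <- shape_sphere(21, 4)
  m2b <- array(FALSE, c(21, 45, 21)); m2b[, 1:21, ] <- m2
  m2b[, 25:45, ][m2] <- TRUE
  expect_equal(max(label_organelles(m2b)), 2L)
  expect_equal(max(label_organelles(array(FALSE, c(1, 4, 4)))), 0L)
})

test_that("skeletons are thin, centred, complete and radius-annotated", {
  m <- shape_tube2d()                       # 6 wide (radius ~3), length 50
  dist <- distance_transform(m, c(1, 1))
  sk <- skeletonize(m, dist)
  br <- label_branches(sk)
  expect_equal(sum(br$tip), 2)
  expect_equal(br$n_branches, 1)
  expect_lt(abs(sum(sk) - 50), 5)           # path voxel count ~ length
  # radius at skeleton ~ tube half-width within one voxel
  expect_lt(max(abs(dist[sk] - 3)), 1.01)

  s <- shape_sphere(21, 6)
  sks <- skeletonize(s, distance_transform(s, c(1, 1, 1)))
  expect_lte(sum(sks), 27)
  w <- which(sks, arr.ind = TRUE)
  expect_true(all(abs(w - 11) <= 3))        # near the centre

  # single-voxel object is its own skeleton
  sv <- array(FALSE, c(1, 5, 5)); sv[1, 3, 3] <- TRUE
  expect_equal(which(skeletonize(sv, distance_transform(sv, c(1, 1)))),
               which(sv))
})

test_that("branch decomposition matches closed-form scene topology", {
  b <- label_branches(skeletonize(shape_plus(), spacing = c(1, 1)))
  expect_gte(sum(b$junction), 1)
  expect_equal(sum(b$tip), 4)
  expect_equal(b$n_branches, 4)

  b2 <- label_branches(skeletonize(shape_y(), spacing = c(1, 1)))
  expect_equal(sum(b2$tip), 3)
  expect_equal(b2$n_branches, 3)

  # every skeleton voxel carries a branch label
  sk <- skeletonize(shape_plus(), spacing = c(1, 1))
  expect_true(all(b$branch_labels[sk] > 0))
})

test_that("voxel-to-node assignment is a nearest-node partition", {
  m <- shape_tube2d(rows = 19:22, cols = 10:49)
  hier <- hierarchy_from_mask(m)
  v2n <- hier$voxel_to_node
  # partition: every mask voxel assigned, background untouched
  expect_true(all(v2n[m] > 0))
  expect_true(all(v2n[!m] == 0))
  # brute-force nearest-node oracle (ties -> lowest node id)
  d <- dim(m)
  nodes <- hier$nodes
  vidx <- which(m)
  co <- organellometry:::coords_from_index(vidx, d)
  for (i in seq(1, length(vidx), by = 17)) {
    dd <- (nodes$z - co[i, 1])^2 + (nodes$y - co[i, 2])^2 + (nodes$x - co[i, 3])^2
    expect_equal(v2n[vidx[i]], nodes$node_id[which.min(round(dd, 9))])
  }
  # single-node organelle: all voxels to that node
  sv <- shape_sphere(9, 2)
  hs <- hierarchy_from_mask(sv, spacing = c(1, 1, 1))
  expect_true(all(hs$voxel_to_node[sv] %in% hs$nodes$node_id))
})

test_that("hierarchy conserves voxels across levels and is deterministic", {
  spec <- scene_seg(3, 150, seed = 21)
  st <- render_timelapse(build_scene(spec))
  enh <- structure_enhance(array(st$data[1, , , ], dim(st$data)[2:4]),
                           derive_scales(st$spacing))
  h1 <- segment_frame(enh, st$spacing)
  h2 <- segment_frame(enh, st$spacing)
  expect_identical(h1$organelle_labels, h2$organelle_labels)
  expect_identical(h1$voxel_to_node, h2$voxel_to_node)

  n_mask <- sum(h1$semantic)
  expect_equal(sum(h1$organelle_labels > 0), n_mask)
  expect_equal(sum(h1$branch_labels > 0), n_mask)
  expect_equal(sum(h1$voxel_to_node > 0), n_mask)
  # voxel branch label equals its node's branch label
  vidx <- which(h1$semantic)
  expect_equal(h1$branch_labels[vidx],
               h1$nodes$branch_id[h1$voxel_to_node[vidx]])
  # node radius equals the distance transform at the node
  nidx <- organellometry:::index_from_coords(
    as.matrix(h1$nodes[, c("z", "y", "x")]), dim(h1$semantic))
  expect_equal(h1$nodes$radius_um, h1$distance_um[nidx])
  # node organelle id matches the label at its coordinate
  expect_equal(h1$nodes$organelle_id, h1$organelle_labels[nidx])
})
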
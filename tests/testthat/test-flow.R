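fake_links <- function(src_coords, vecs, costs) {
  markers <- data.frame(marker_id = seq_len(nrow(src_coords)),
                        z = src_coords[, 1], y = src_coords[, 2],
                        x = src_coords[, 3], radius_um = 1)
  links <- data.frame(source = seq_len(nrow(src_coords)),
                      target = seq_len(nrow(src_coords)),
                      cost = costs, dz = vecs[, 1], dy = vecs[, 2],
                      dx = vecs[, 3])
  list(markers = markers,
       linkset = structure(list(direction = "forward", links = links,
                                unmatched = integer()), class = "LinkageSet"))
}

test_that("flow interpolation is convex and respects its weight formula", {
  # identical link vectors: any CoI reproduces them exactly
  fx <- fake_links(cbind(0, c(2, 6, 9), c(3, 3, 8)),
                   matrix(rep(c(0, 0, 1), 3), 3, byrow = TRUE), c(0.2, -1, 3))
  ff <- interpolate_flow(cbind(0, c(4, 8), c(4, 6)), fx$linkset, fx$markers,
                         spacing = c(1, 1), max_travel_um = 20)
  expect_equal(unname(ff$vectors_um),
               matrix(rep(c(0, 0, 1), 2), 2, byrow = TRUE), tolerance = 1e-12)
  expect_equal(ff$support, c(3L, 3L))

  # no marker in range: zero vector, support zero
  ff0 <- interpolate_flow(cbind(0, 50, 50), fx$linkset, fx$markers,
                          spacing = c(1, 1), max_travel_um = 2)
  expect_equal(unname(ff0$vectors_um), matrix(0, 1, 3))
  expect_equal(ff0$support, 0L)

  # two equidistant equal-cost links average their vectors
  f2 <- fake_links(cbind(0, c(2, 8), c(5, 5)),
                   rbind(c(0, 1, 0), c(0, 0, 1)), c(1, 1))
  fm <- interpolate_flow(cbind(0, 5, 5), f2$linkset, f2$markers,
                         spacing = c(1, 1), max_travel_um = 10)
  expect_equal(unname(fm$vectors_um), matrix(c(0, 0.5, 0.5), 1), tolerance = 1e-9)

  # convex hull bound: every component within the contributing range
  set.seed(8)
  f3 <- fake_links(cbind(0, runif(6, 0, 10), runif(6, 0, 10)),
                   cbind(0, runif(6, -1, 1), runif(6, -1, 1)), rnorm(6))
  fc <- interpolate_flow(cbind(0, runif(9, 0, 10), runif(9, 0, 10)),
                         f3$linkset, f3$markers, c(1, 1), max_travel_um = 30)
  for (ax in 2:3) {
    rng <- range(f3$linkset$links[[c("dz", "dy", "dx")[ax]]])
    expect_true(all(fc$vectors_um[, ax] >= rng[1] - 1e-9 &
                      fc$vectors_um[, ax] <= rng[2] + 1e-9))
  }
})

test_that("static scenes yield stationary tracks and identity voxel fates", {
  spec <- scene_blob_field(speed_vox = 0, seed = 17, n_frames = 3)
  st <- render_timelapse(build_scene(spec))
  res <- run_pipeline(st, pipeline_config())
  tr <- res$tracks
  disp <- tapply(seq_len(nrow(tr)), tr$track_id, function(ix) {
    g <- tr[ix, ]
    max(abs(g$x - g$x[1]) + abs(g$y - g$y[1]))
  })
  expect_lt(mean(disp), 0.25)

  h1 <- res$hierarchies[[1]]; h2 <- res$hierarchies[[2]]
  vidx <- which(h1$semantic)
  co <- organellometry:::coords_from_index(vidx, dim(h1$semantic))
  ff <- interpolate_flow(co, res$tracking$links[[1]]$forward,
                         res$tracking$markers[[1]], st$spacing)
  fate <- match_voxels(h1, h2, ff)
  same <- fate$voxel_t1 == fate$voxel_t
  expect_gt(mean(same, na.rm = TRUE), 0.8)
})

test_that("rigid translation is recovered to sub-voxel accuracy", {
  for (speed in c(0.5, 1.0)) {
    spec <- scene_blob_field(speed_vox = speed, seed = 7, n_frames = 6)
    st <- render_timelapse(build_scene(spec))
    res <- run_pipeline(st, pipeline_config())
    tr <- res$tracks
    m <- merge(tr[tr$frame == 1, ], tr[tr$frame == 6, ], by = "track_id")
    err <- mean(sqrt((m$x.y - m$x.x - speed * 5)^2 + (m$y.y - m$y.x)^2))
    expect_lt(err, 0.5)
  }
})

test_that("rotation produces track steps proportional to the lever arm", {
  spec <- scene_blob_field(seed = 11, rotation = 0.05, n_frames = 5)
  st <- render_timelapse(build_scene(spec))
  res <- run_pipeline(st, pipeline_config())
  tr <- res$tracks
  piv <- c(4.8, 6.0) / SP_TEST
  m <- merge(tr[tr$frame == 1, ], tr[tr$frame == 2, ], by = "track_id")
  r <- sqrt((m$y.x - piv[1])^2 + (m$x.x - piv[2])^2)
  step <- sqrt((m$y.y - m$y.x)^2 + (m$x.y - m$x.x)^2)
  sel <- r > 10          # ignore short lever arms where quantization dominates
  expect_lt(abs(mean(step[sel] / (r[sel] * 0.05)) - 1), 0.2)
})

test_that("integer-voxel shifts give exact fate maps; lost objects unmatch", {
  m1 <- array(FALSE, c(1, 20, 26)); m1[1, 6:10, 4:12] <- TRUE
  m2 <- array(FALSE, c(1, 20, 26)); m2[1, 6:10, 7:15] <- TRUE
  h1 <- hierarchy_from_mask(m1); h2 <- hierarchy_from_mask(m2)
  vidx <- which(m1)
  co <- organellometry:::coords_from_index(vidx, dim(m1))
  ff <- structure(list(coords = co,
                       vectors_um = cbind(0, 0, rep(3, length(vidx))),
                       support = rep(1L, length(vidx)),
                       direction = "forward"), class = "FlowField")
  fate <- match_voxels(h1, h2, ff)
  expect_true(all(!is.na(fate$voxel_t1)))
  shifted <- organellometry:::index_from_coords(co + rep(c(0, 0, 3), each = nrow(co)),
                                                dim(m1))
  expect_equal(fate$voxel_t1, shifted)

  # object that disappears leaves its voxels unmatched
  fate2 <- match_voxels(h1, suppressWarnings(
    hierarchy_from_mask(array(FALSE, dim(m1)))), ff)
  expect_true(all(is.na(fate2$voxel_t1)))
})

test_that("forward-then-backward displacement returns near the start", {
  spec <- scene_blob_field(speed_vox = 0.5, seed = 19, n_frames = 3)
  st <- render_timelapse(build_scene(spec))
  res <- run_pipeline(st, pipeline_config())
  h1 <- res$hierarchies[[1]]
  seeds <- as.matrix(h1$nodes[, c("z", "y", "x")])
  fwd <- interpolate_flow(seeds, res$tracking$links[[1]]$forward,
                          res$tracking$markers[[1]], st$spacing)
  moved <- seeds + sweep(fwd$vectors_um, 2, c(1, SP_TEST, SP_TEST), `/`)
  bwd <- interpolate_flow(moved, res$tracking$links[[1]]$backward,
                          res$tracking$markers[[2]], st$spacing)
  back <- moved + sweep(bwd$vectors_um, 2, c(1, SP_TEST, SP_TEST), `/`)
  err <- sqrt(rowSums((back - seeds)^2))
  expect_lt(mean(err), 0.5)
})
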
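test_that("static scenes have zero motility everywhere", {
  spec <- scene_blob_field(speed_vox = 0, seed = 23, n_frames = 3)
  res <- run_scene(spec)
  vx <- res$tables$voxel
  mid <- vx[vx$frame == 1, ]
  expect_lt(mean(mid$lin_vel_mag_12), 0.02)
  expect_lt(mean(mid$rel_lin_vel_mag_12), 0.03)
  expect_lt(mean(mid$ref_lin_vel_mag_12), 0.02)
})

test_that("uniform translation speed is recovered from voxel velocities", {
  for (speed in c(0.5, 1.0)) {
    spec <- scene_blob_field(speed_vox = speed, seed = 7, n_frames = 5)
    res <- run_scene(spec)
    vx <- res$tables$voxel
    sel <- vx$frame %in% 1:3
    est <- sqrt(mean(vx$lin_vel_z_12[sel], na.rm = TRUE)^2 +
                  mean(vx$lin_vel_y_12[sel], na.rm = TRUE)^2 +
                  mean(vx$lin_vel_x_12[sel], na.rm = TRUE)^2)
    expect_lt(abs(est - speed * SP_TEST) / (speed * SP_TEST), 0.10)
  }
})

test_that("pivot-relative angular velocity recovers the rotation rate", {
  ests <- vapply(c(7, 13, 21, 29, 37, 45), function(sd) {
    res <- run_scene(scene_rot_capsule(0.1, sd))
    tube_org <- res$hierarchies[[1]]$organelle_labels[1, 37, 40]
    est_angular_rate(res, tube_org)
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.1) / 0.1, 0.15)
})

test_that("node vergence reads divergence of the surrounding flow", {
  s <- shape_disc(25, 8)
  h <- hierarchy_from_mask(s)
  vidx <- which(s)
  co <- organellometry:::coords_from_index(vidx, dim(s))
  nco <- as.matrix(h$nodes[, c("z", "y", "x")])
  # uniform flow: vergence ~ 0
  nf <- node_features(h, matrix(rep(c(0, 0.3, 0.7), each = length(vidx)),
                                ncol = 3),
                      matrix(rep(c(0, 0.3, 0.7), each = nrow(nco)), ncol = 3))
  expect_lt(max(abs(nf$vergence)), 1e-3)
  # radially expanding field v = k * (p - center): vergence ~ +k * mean|r|
  k <- 0.2
  ctr <- colMeans(co)
  fv <- k * sweep(co, 2, ctr)
  fn <- k * sweep(nco, 2, ctr)
  nf2 <- node_features(h, fv, fn)
  # against the analytic expectation per node
  for (i in seq_len(nrow(nco))) {
    sel <- which(h$voxel_to_node[vidx] == h$nodes$node_id[i])
    u <- sweep(co[sel, , drop = FALSE], 2, nco[i, ])
    nu <- sqrt(rowSums(u^2)); ok <- nu > 0
    if (!any(ok)) next
    expected <- mean(k * nu[ok])
    expect_lt(abs(nf2$vergence[i] - expected) / max(expected, 1e-6), 0.2)
  }
  # thickness is twice the node radius
  expect_equal(nf$thickness_um, 2 * h$nodes$radius_um)
})

test_that("branch geometry: straight, semicircular and capsule closed forms", {
  # straight branch
  m <- shape_tube2d(rows = 19:22, cols = 8:51)
  h <- hierarchy_from_mask(m, spacing = c(1, 1))
  bf <- branch_features(h)
  expect_equal(nrow(bf), 1L)
  expect_lt(abs(bf$branch_tortuosity - 1), 0.05)

  # semicircular arc: tortuosity ~ pi/2
  spec <- scene_spec(shape = c(1, 1, 60, 80), spacing = c(0.1, 0.1),
    objects = list(arc_object(c(0, 1.8, 4.0), arc_radius_um = 2.2,
                              tube_radius_um = 0.25, theta0 = 0, theta1 = pi,
                              intensity = 100)),
    psf_sigma_um = 0, noise = list(poisson = FALSE, gaussian_sd = 0),
    background = 0, seed = 1)
  gt <- build_scene(spec)
  h2 <- hierarchy_from_mask(gt$semantic[[1]], spacing = c(0.1, 0.1))
  bf2 <- branch_features(h2)
  big <- bf2[which.max(bf2$branch_length), ]
  expect_lt(abs(big$branch_tortuosity - pi / 2) / (pi / 2), 0.05)

  # capsule 10 um long, radius 0.5 um: aspect ratio ~ 10
  spec3 <- scene_spec(shape = c(1, 1, 40, 130), spacing = c(0.1, 0.1),
    objects = list(tube_object(c(0, 2.03, 1.2), c(0, 2.03, 11.2), 0.5, 100)),
    psf_sigma_um = 0, noise = list(poisson = FALSE, gaussian_sd = 0),
    background = 0, seed = 1)
  h3 <- hierarchy_from_mask(build_scene(spec3)$semantic[[1]], spacing = c(0.1, 0.1))
  bf3 <- branch_features(h3)
  expect_lt(abs(bf3$branch_aspect_ratio[which.max(bf3$branch_length)] - 10) / 10,
            0.15)
})

test_that("organelle morphology: sphere, exact volume, L-shape solidity", {
  s <- shape_sphere(21, 7)
  h <- hierarchy_from_mask(s, spacing = c(0.2, 0.2, 0.2))
  of <- organelle_features(h)
  expect_gte(of$solidity, 0.95)
  eigs <- c(of$inertia_tensor_eig_sorted_min, of$inertia_tensor_eig_sorted_mid,
            of$inertia_tensor_eig_sorted_max)
  expect_lt(diff(range(eigs)) / mean(eigs), 0.10)
  expect_equal(of$volume, sum(s) * 0.2^3)

  # L-shaped solid: solidity equals voxel count over the analytic hull count
  L <- array(FALSE, c(1, 30, 30))
  L[1, 5:25, 5:10] <- TRUE
  L[1, 20:25, 5:25] <- TRUE
  hL <- hierarchy_from_mask(L, spacing = c(1, 1))
  ofL <- organelle_features(hL)
  # independent hull: pentagon (4,4) (4,9) (19,24) (24,24) (24,4) in (y,x)0-based
  verts <- rbind(c(4, 4), c(4, 9), c(19, 24), c(24, 24), c(24, 4))
  inside <- function(p) {
    k <- nrow(verts); sgn <- 0
    for (i in seq_len(k)) {
      a <- verts[i, ]; b <- verts[if (i == k) 1 else i + 1, ]
      cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      if (abs(cr) < 1e-9) next
      if (sgn == 0) sgn <- sign(cr)
      else if (sign(cr) != sgn) return(FALSE)
    }
    TRUE
  }
  cnt <- 0
  for (y in 4:24) for (x in 4:24) if (inside(c(y, x))) cnt <- cnt + 1
  expect_lt(abs(ofL$solidity - sum(L) / cnt), 0.02 * ofL$solidity)
})

test_that("morphology is invariant to 90-degree rotations and spacing rescale", {
  m <- shape_y()
  h <- hierarchy_from_mask(m, spacing = c(1, 1))
  mr <- array(FALSE, c(1, 60, 60))
  mr[1, , ] <- t(m[1, , ])[60:1, ]         # 90-degree rotation
  hr <- hierarchy_from_mask(mr, spacing = c(1, 1))
  of <- organelle_features(h); ofr <- organelle_features(hr)
  expect_lt(abs(of$solidity - ofr$solidity) / of$solidity, 0.05)
  expect_lt(abs(of$extent - ofr$extent) / of$extent, 0.05)
  bf <- branch_features(h); bfr <- branch_features(hr)
  expect_lt(abs(sum(bf$branch_length) - sum(bfr$branch_length)) /
              sum(bf$branch_length), 0.05)

  # rescaling spacing by k scales lengths by k, leaves ratios unchanged
  h2 <- hierarchy_from_mask(m, spacing = c(3, 3))
  bf2 <- branch_features(h2)
  expect_equal(bf2$branch_length, bf$branch_length * 3, tolerance = 1e-9)
  expect_equal(bf2$branch_tortuosity, bf$branch_tortuosity, tolerance = 1e-9)
  expect_equal(bf2$branch_aspect_ratio, bf$branch_aspect_ratio, tolerance = 1e-9)
  of2 <- organelle_features(h2)
  expect_equal(of2$solidity, of$solidity, tolerance = 1e-9)
  expect_equal(of2$extent, of$extent, tolerance = 1e-9)
})

test_that("morphology is bitwise stable across duplicated static frames", {
  spec <- scene_blob_field(speed_vox = 0, seed = 29, n_frames = 2)
  spec$noise <- list(poisson = FALSE, gaussian_sd = 0)
  res <- run_scene(spec)
  br <- res$tables$branch
  b1 <- br[br$frame == 0, c("branch_length", "branch_tortuosity", "volume")]
  b2 <- br[br$frame == 1, c("branch_length", "branch_tortuosity", "volume")]
  rownames(b1) <- rownames(b2) <- NULL
  expect_identical(b1, b2)
})

test_that("aggregation matches a brute-force two-pass oracle", {
  child <- data.frame(branch_id = c(1, 1, 1, 2, 2, 3),
                      len = c(3, 4, 5, 1, 2, 7), v = c(1, 1, 1, 2, 8, NA))
  agg <- aggregate_features(child, "branch_id", c("len", "v"),
                            stats = c("mean", "std", "sum", "median"),
                            child_level = "node")
  expect_equal(agg$node_sum_len, c(12, 3, 7))
  expect_equal(agg$node_std_v, c(0, stats::sd(c(2, 8)), NA))
  expect_equal(agg$node_median_len, c(4, 1.5, 7))
  # organelle with branches of length 3 and 4: sum 7
  par <- data.frame(organelle_id = c(1, 1), branch_length = c(3, 4))
  a2 <- aggregate_features(par, "organelle_id", "branch_length",
                           stats = "sum", child_level = "branch")
  expect_equal(a2$branch_sum_branch_length, 7)
  # two-pass oracle on random data
  set.seed(31)
  rnd <- data.frame(g = sample(1:4, 40, TRUE), f = rnorm(40))
  a3 <- aggregate_features(rnd, "g", "f", stats = c("mean", "std"),
                           child_level = "x")
  for (g in 1:4) {
    expect_equal(a3$x_mean_f[a3$g == g], mean(rnd$f[rnd$g == g]))
    expect_equal(a3$x_std_f[a3$g == g], stats::sd(rnd$f[rnd$g == g]))
  }
})
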
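# Shared fixtures: all built in code, deterministic under fixed seeds.

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# voxelized shapes on a (1, ny, nx) grid ------------------------------------

shape_tube2d <- function(ny = 40, nx = 60, rows = 18:23, cols = 6:55) {
  m <- array(FALSE, c(1, ny, nx))
  m[1, rows, cols] <- TRUE
  m
}

shape_plus <- function(n = 41, arm = 19:23, span = 3:39) {
  m <- array(FALSE, c(1, n, n))
  m[1, arm, span] <- TRUE
  m[1, span, arm] <- TRUE
  m
}

shape_y <- function() {
  m <- array(FALSE, c(1, 60, 60))
  m[1, 30:33, 5:30] <- TRUE
  for (k in 0:20) {
    m[1, (30:33) - k, 30 + k + (-1:1)] <- TRUE
    m[1, (30:33) + k, 30 + k + (-1:1)] <- TRUE
  }
  m
}

shape_ring <- function(n = 41, r_in = 10, r_out = 14) {
  m <- array(FALSE, c(1, n, n))
  c0 <- (n + 1) / 2
  for (y in 1:n) for (x in 1:n) {
    r <- sqrt((y - c0)^2 + (x - c0)^2)
    if (r >= r_in && r <= r_out) m[1, y, x] <- TRUE
  }
  m
}

shape_sphere <- function(n = 21, r = 6) {
  m <- array(FALSE, c(n, n, n))
  c0 <- (n + 1) / 2
  for (z in 1:n) for (y in 1:n) for (x in 1:n)
    if ((z - c0)^2 + (y - c0)^2 + (x - c0)^2 <= r^2) m[z, y, x] <- TRUE
  m
}

shape_disc <- function(n = 31, r = 10) {
  m <- array(FALSE, c(1, n, n))
  c0 <- (n + 1) / 2
  for (y in 1:n) for (x in 1:n)
    if ((y - c0)^2 + (x - c0)^2 <= r^2) m[1, y, x] <- TRUE
  m
}

hierarchy_from_mask <- function(mask, spacing = c(1, 1)) {
  resp <- array(0, dim(mask))
  resp[mask] <- 1
  enh <- structure(list(response = resp, argmax_scale = array(0L, dim(mask))),
                   class = "EnhancedFrame")
  segment_frame(enh, spacing, threshold = 0.5)
}

# synthetic scenes -----------------------------------------------------------

SP_TEST <- 0.15

# segmentation-benchmark scene: tube of given voxel radius + two blobs
scene_seg <- function(r_vox, intensity, seed) {
  r_um <- r_vox * SP_TEST
  scene_spec(shape = c(1, 1, 72, 90), spacing = c(SP_TEST, SP_TEST),
    objects = list(
      tube_object(c(0, 3.3, 2.4), c(0, 3.3, 11.1), r_um, intensity),
      blob_object(c(0, 7.8, 4.5), max(0.3, r_um), intensity),
      blob_object(c(0, 7.8, 9.0), 0.45, intensity)),
    psf_sigma_um = 0.1, noise = list(poisson = TRUE, gaussian_sd = 2),
    background = 10, seed = seed)
}

# tracking scene: field of round organelles of distinct radii, rigid motion
scene_blob_field <- function(speed_vox = 0, seed = 7, rotation = 0,
                             n_frames = 5) {
  piv <- c(0, 4.8, 6.0)
  tr_um <- c(0, 0, speed_vox * SP_TEST)
  pos <- list(c(2.5, 2.5), c(2.8, 6.2), c(3.4, 9.3), c(5.0, 4.0), c(5.4, 7.6),
              c(6.8, 2.7), c(7.2, 6.0), c(7.0, 9.2), c(4.6, 11.0))
  rad <- c(0.30, 0.45, 0.35, 0.55, 0.28, 0.40, 0.50, 0.33, 0.42)
  objs <- lapply(seq_along(pos), function(i)
    blob_object(c(0, pos[[i]][1], pos[[i]][2]), rad[i], 150,
                translation_um = tr_um, rotation_rad = rotation,
                pivot_um = piv))
  scene_spec(shape = c(n_frames, 1, 72, 104), spacing = c(SP_TEST, SP_TEST),
    objects = objs, psf_sigma_um = 0.1,
    noise = list(poisson = TRUE, gaussian_sd = 2), background = 10,
    seed = seed)
}

# rotating elongated organelle (angular-rate recovery)
scene_rot_capsule <- function(omega, seed) {
  ctr <- c(0, 5.4, 6.0)
  scene_spec(shape = c(5, 1, 72, 80), spacing = c(SP_TEST, SP_TEST),
    objects = list(
      tube_object(c(0, 5.4, 3.8), c(0, 5.4, 8.2), 0.35, 150,
                  rotation_rad = omega, pivot_um = ctr),
      blob_object(c(0, 2.2, 3.0), 0.45, 150),
      blob_object(c(0, 2.4, 8.6), 0.3, 150)),
    psf_sigma_um = 0.1, noise = list(poisson = TRUE, gaussian_sd = 2),
    background = 10, seed = seed)
}

run_scene <- function(spec, config = pipeline_config(), out_dir = NULL) {
  run_pipeline(render_timelapse(build_scene(spec)), config, out_dir = out_dir)
}

# angular-rate estimate from the voxel table: median of the pivot-relative
# angular speed over the higher-lever half of the voxels (the per-voxel
# angle is noise-dominated near the pivot)
est_angular_rate <- function(res, tube_org) {
  vx <- res$tables$voxel
  sel <- vx$frame %in% 1:3 & vx$organelle_id == tube_org &
    !is.na(vx$rel_ang_vel_mag_12)
  v <- vx[sel, ]
  hi <- v$rel_lin_vel_mag_12 >= stats::median(v$rel_lin_vel_mag_12)
  stats::median(v$rel_ang_vel_mag_12[hi])
}
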
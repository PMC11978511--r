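# Label-independent motion-capture markers: detection on the distance
# transform, stats/Hu feature vectors, and frame-to-frame best-match linkage
# through a z-scored summed cost matrix.

#' Detect motion-capture markers in one frame
#'
#' Markers are local maxima of the distance transform restricted to the
#' semantic mask, with an adaptive exclusion footprint whose per-axis
#' half-width equals the local radius in voxels (at least 1), so thick
#' regions yield sparse markers and thin regions dense ones. Plateau maxima
#' keep the lowest-index voxel. Every organelle receives at least one marker
#' (its maximum-distance voxel as fallback). Detection never looks at
#' instance labels, keeping tracking label-independent.
#'
#' @param hierarchy a `LabelHierarchy`.
#' @param raw optional raw intensity frame; when given, the sub-voxel
#'   refinement weights are the background-subtracted intensities (photon
#'   centroid), otherwise the distance transform.
#' @return data.frame: `marker_id`, `z`, `y`, `x` (0-based, sub-voxel
#'   refined centre), `zi`, `yi`, `xi` (detection voxel), `radius_um`.
#' @export
detect_markers <- function(hierarchy, raw = NULL) {
  mask <- hierarchy$semantic
  d <- dim(mask)
  dist <- hierarchy$distance_um
  sp3 <- spacing3_of(hierarchy$spacing)
  empty <- data.frame(marker_id = integer(), z = integer(), y = integer(),
                      x = integer(), radius_um = numeric())
  if (!any(mask)) return(empty)
  # candidates: neighbourhood maxima of the distance transform (plateaus
  # included), then greedy non-maximum suppression with the adaptive
  # footprint: candidates are visited by decreasing distance (ties by
  # ascending index, so plateau maxima resolve to the lowest-index voxel)
  # and accepted unless an already accepted marker lies within the
  # candidate's per-axis exclusion half-width max(1, radius in voxels).
  cand <- local_max_26(mask, dist, d)
  cand <- cand[order(-dist[cand], cand)]
  cco <- coords_from_index(cand, d)
  accepted <- integer()
  acc_co <- NULL
  for (k in seq_along(cand)) {
    r_um <- dist[cand[k]]
    w <- pmax(1, round(r_um / sp3))
    w[d == 1] <- 0
    if (!is.null(acc_co)) {
      close <- abs(acc_co[, 1] - cco[k, 1]) <= w[1] &
        abs(acc_co[, 2] - cco[k, 2]) <= w[2] &
        abs(acc_co[, 3] - cco[k, 3]) <= w[3]
      if (any(close)) next
    }
    accepted <- c(accepted, cand[k])
    acc_co <- rbind(acc_co, cco[k, ])
  }
  # fallback: organelles without a marker get their max-distance voxel
  org <- hierarchy$organelle_labels
  have <- unique(org[accepted])
  for (o in setdiff(seq_len(max(org)), have)) {
    vidx <- which(org == o)
    accepted <- c(accepted, vidx[which.max(dist[vidx])])
  }
  accepted <- sort(accepted)
  co <- coords_from_index(accepted, d)
  # sub-voxel refinement: weighted centroid inside the footprint, weights
  # being background-subtracted intensity (photon centroid) when the raw
  # frame is available, else the distance transform; the detection voxel is
  # kept for patch extraction, the refined centre drives all geometry
  # (costs, displacements, flow queries)
  bg <- if (!is.null(raw)) stats::median(raw) else NULL
  ref <- matrix(NA_real_, length(accepted), 3)
  for (k in seq_along(accepted)) {
    r_um <- dist[accepted[k]]
    # half again wider than the detection footprint: captures the PSF tails
    # that carry the sub-voxel position without reaching into neighbours
    w <- pmax(1, round(1.5 * r_um / sp3))
    w[d == 1] <- 0
    zr <- max(1, co[k, 1] + 1 - w[1]):min(d[1], co[k, 1] + 1 + w[1])
    yr <- max(1, co[k, 2] + 1 - w[2]):min(d[2], co[k, 2] + 1 + w[2])
    xr <- max(1, co[k, 3] + 1 - w[3]):min(d[3], co[k, 3] + 1 + w[3])
    sub <- as.matrix(expand.grid(z = zr, y = yr, x = xr)) - 1L
    ii <- index_from_coords(sub, d)
    wt <- if (!is.null(raw)) pmax(raw[ii] - bg, 0) else dist[ii]
    wt[wt < 0 | !is.finite(wt)] <- 0
    ref[k, ] <- if (sum(wt) > 0) colSums(sub * wt) / sum(wt) else co[k, ]
  }
  data.frame(marker_id = seq_along(accepted),
             z = ref[, 1], y = ref[, 2], x = ref[, 3],
             zi = co[, 1], yi = co[, 2], xi = co[, 3],
             radius_um = dist[accepted])
}

# 26-neighbourhood local maxima (>= all neighbours) of dist within mask
local_max_26 <- function(mask, dist, d) {
  idx <- which(mask)
  offs <- neighbor_offsets(d)
  keep <- rep(TRUE, length(idx))
  co <- coords_from_index(idx, d)
  for (r in seq_len(nrow(offs))) {
    z <- co[, 1] + offs$dz[r]; y <- co[, 2] + offs$dy[r]; x <- co[, 3] + offs$dx[r]
    ok <- z >= 0 & z < d[1] & y >= 0 & y < d[2] & x >= 0 & x < d[3]
    j <- index_from_coords(cbind(z[ok], y[ok], x[ok]), d)
    bad <- dist[j] > dist[idx[ok]]
    keep[which(ok)[bad]] <- FALSE
  }
  idx[keep]
}

# first six Hu moment invariants of a 2D patch
hu6 <- function(patch) {
  patch <- rbind(patch)
  m00 <- sum(patch)
  if (m00 <= 0) return(rep(0, 6))
  ny <- nrow(patch); nx <- ncol(patch)
  ys <- (seq_len(ny) - 1); xs <- (seq_len(nx) - 1)
  m10 <- sum(ys * rowSums(patch)); m01 <- sum(xs * colSums(patch))
  cy <- m10 / m00; cx <- m01 / m00
  dy <- ys - cy; dx <- xs - cx
  mu <- function(p, q) sum(outer(dy^p, dx^q) * patch)
  n_ <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  e20 <- n_(2, 0); e02 <- n_(0, 2); e11 <- n_(1, 1)
  e30 <- n_(3, 0); e03 <- n_(0, 3); e21 <- n_(2, 1); e12 <- n_(1, 2)
  c(e20 + e02,
    (e20 - e02)^2 + 4 * e11^2,
    (e30 - 3 * e12)^2 + (3 * e21 - e03)^2,
    (e30 + e12)^2 + (e21 + e03)^2,
    (e30 - 3 * e12) * (e30 + e12) * ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
      (3 * e21 - e03) * (e21 + e03) * (3 * (e30 + e12)^2 - (e21 + e03)^2),
    (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
      4 * e11 * (e30 + e12) * (e21 + e03))
}

signed_log10 <- function(x) sign(x) * log10(abs(x) + 1e-30)

# max-intensity projections of a 3D patch: xy (along z), xz (along y), yz (along x)
patch_projections <- function(patch) {
  list(xy = apply(patch, c(2, 3), max),
       xz = apply(patch, c(1, 3), max),
       yz = apply(patch, c(1, 2), max))
}

#' Fill marker stats and Hu feature vectors
#'
#' The bounding box of each marker has per-axis half-width equal to its
#' radius in voxels (box side two radii), clipped to the frame. The stats
#' vector holds mean and variance of the raw and the enhanced image within
#' the box. Hu vectors hold the first six Hu moment invariants, computed on
#' the raw and enhanced patches (2D), or on xy/xz/yz maximum-intensity
#' projections of the box (3D: 6 x 3 planes x 2 images = 36 values), stored
#' as `sign(phi) * log10(|phi| + 1e-30)` for scale stability.
#'
#' @param markers marker table from [detect_markers()].
#' @param raw raw intensity frame, (z, y, x) array.
#' @param enhanced `EnhancedFrame` or response array.
#' @param spacing voxel spacing (microns).
#' @return markers with matrix columns `stats_vec` (n x 4) and `hu_vec`
#'   (n x 12 in 2D, n x 36 in 3D).
#' @export
marker_feature_vectors <- function(markers, raw, enhanced, spacing) {
  resp <- if (inherits(enhanced, "EnhancedFrame")) enhanced$response else enhanced
  d <- dim(raw)
  sp3 <- spacing3_of(spacing)
  flat <- is_flat(d)
  n <- nrow(markers)
  stats_vec <- matrix(0, n, 4)
  hu_vec <- matrix(0, n, if (flat) 12 else 36)
  pvar <- function(x) mean((x - mean(x))^2)
  for (i in seq_len(n)) {
    co <- c(markers$zi[i], markers$yi[i], markers$xi[i])
    w <- pmax(1, round(markers$radius_um[i] / sp3))
    w[d == 1] <- 0
    zr <- max(1, co[1] + 1 - w[1]):min(d[1], co[1] + 1 + w[1])
    yr <- max(1, co[2] + 1 - w[2]):min(d[2], co[2] + 1 + w[2])
    xr <- max(1, co[3] + 1 - w[3]):min(d[3], co[3] + 1 + w[3])
    praw <- raw[zr, yr, xr, drop = FALSE]
    penh <- resp[zr, yr, xr, drop = FALSE]
    stats_vec[i, ] <- c(mean(praw), pvar(praw), mean(penh), pvar(penh))
    if (flat) {
      hu_vec[i, ] <- signed_log10(c(hu6(array(praw, dim(praw)[2:3])),
                                    hu6(array(penh, dim(penh)[2:3]))))
    } else {
      pr <- patch_projections(array(praw, c(length(zr), length(yr), length(xr))))
      pe <- patch_projections(array(penh, c(length(zr), length(yr), length(xr))))
      hu_vec[i, ] <- signed_log10(c(hu6(pr$xy), hu6(pr$xz), hu6(pr$yz),
                                    hu6(pe$xy), hu6(pe$xz), hu6(pe$yz)))
    }
  }
  markers$stats_vec <- stats_vec
  markers$hu_vec <- hu_vec
  markers
}

zscore_over <- function(m, adm) {
  v <- m[adm]
  if (length(v) < 1) return(m * 0)
  mu <- mean(v); sd <- stats::sd(v)
  if (!is.finite(sd) || sd == 0) { m[] <- 0; return(m) }
  (m - mu) / sd
}

#' Build the marker-linkage cost matrix for a frame pair
#'
#' Three difference blocks over admissible pairs (physical distance within
#' the maximum travel range): Euclidean coordinate distance, Euclidean
#' distance of stats vectors, Euclidean distance of Hu vectors. Each block
#' is z-score normalised over the admissible entries (all zeros if the block
#' has no variance) and the blocks are summed with the given weights.
#'
#' @param markers_t,markers_t1 feature-filled marker tables for frames t and
#'   t+1.
#' @param spacing voxel spacing (microns).
#' @param max_travel_um maximum physical travel per frame (microns).
#' @param weights `(w_dist, w_stats, w_hu)` block weights.
#' @return list with `cost` (matrix, `Inf` where inadmissible), `admissible`
#'   (logical matrix), `disp_um` (list of displacement components
#'   target - source, microns).
#' @export
build_cost_matrix <- function(markers_t, markers_t1, spacing,
                              max_travel_um = 1.0, weights = c(1, 1, 1)) {
  stopifnot(nrow(markers_t) > 0, nrow(markers_t1) > 0)
  sp3 <- spacing3_of(spacing)
  a <- phys_coords(as.matrix(markers_t[, c("z", "y", "x")]), sp3)
  b <- phys_coords(as.matrix(markers_t1[, c("z", "y", "x")]), sp3)
  dz <- outer(a[, 1], b[, 1], function(u, v) v - u)
  dy <- outer(a[, 2], b[, 2], function(u, v) v - u)
  dx <- outer(a[, 3], b[, 3], function(u, v) v - u)
  D <- sqrt(dz^2 + dy^2 + dx^2)
  adm <- D <= max_travel_um
  pair_dist <- function(A, B) {
    s <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    sqrt(pmax(s, 0))
  }
  Ds <- pair_dist(markers_t$stats_vec, markers_t1$stats_vec)
  Dh <- pair_dist(markers_t$hu_vec, markers_t1$hu_vec)
  cost <- weights[1] * zscore_over(D, adm) + weights[2] * zscore_over(Ds, adm) +
    weights[3] * zscore_over(Dh, adm)
  cost[!adm] <- Inf
  list(cost = cost, admissible = adm,
       disp_um = list(dz = dz, dy = dy, dx = dx))
}

#' Link markers by bidirectional best match
#'
#' Each frame-t marker links to its cheapest admissible frame-t+1 marker
#' (forward) and vice versa (backward); no global assignment is solved, so
#' 1-to-1, 1-to-n and n-to-1 matches all arise naturally. Ties break to the
#' lowest index.
#'
#' @param cm cost structure from [build_cost_matrix()].
#' @return list of two `LinkageSet`s (`forward`, `backward`), each with a
#'   `links` data.frame (`source`, `target`, `cost`, `dz`, `dy`, `dx`
#'   microns) and an `unmatched` index vector.
#' @export
link_best_match <- function(cm) {
  nr <- nrow(cm$cost); nc <- ncol(cm$cost)
  fwd_links <- NULL; fwd_un <- integer()
  for (i in seq_len(nr)) {
    if (!any(cm$admissible[i, ])) { fwd_un <- c(fwd_un, i); next }
    j <- which.min(cm$cost[i, ])
    fwd_links <- rbind(fwd_links, data.frame(
      source = i, target = j, cost = cm$cost[i, j],
      dz = cm$disp_um$dz[i, j], dy = cm$disp_um$dy[i, j], dx = cm$disp_um$dx[i, j]))
  }
  bwd_links <- NULL; bwd_un <- integer()
  for (j in seq_len(nc)) {
    if (!any(cm$admissible[, j])) { bwd_un <- c(bwd_un, j); next }
    i <- which.min(cm$cost[, j])
    bwd_links <- rbind(bwd_links, data.frame(
      source = j, target = i, cost = cm$cost[i, j],
      dz = -cm$disp_um$dz[i, j], dy = -cm$disp_um$dy[i, j], dx = -cm$disp_um$dx[i, j]))
  }
  empty <- data.frame(source = integer(), target = integer(), cost = numeric(),
                      dz = numeric(), dy = numeric(), dx = numeric())
  list(
    forward = structure(list(direction = "forward",
                             links = if (is.null(fwd_links)) empty else fwd_links,
                             unmatched = fwd_un), class = "LinkageSet"),
    backward = structure(list(direction = "backward",
                              links = if (is.null(bwd_links)) empty else bwd_links,
                              unmatched = bwd_un), class = "LinkageSet"))
}

#' Detect, featurize and link markers for a whole timelapse
#'
#' @param hierarchies list of per-frame `LabelHierarchy`.
#' @param raw_frames list of per-frame raw arrays.
#' @param enhanced_frames list of per-frame `EnhancedFrame`s.
#' @param spacing voxel spacing (microns).
#' @param max_travel_um maximum travel per frame (microns).
#' @param weights cost block weights.
#' @return list with `markers` (per frame) and `links` (per frame pair,
#'   each holding `forward` and `backward` LinkageSets).
#' @export
track_markers <- function(hierarchies, raw_frames, enhanced_frames, spacing,
                          max_travel_um = 1.0, weights = c(1, 1, 1)) {
  nT <- length(hierarchies)
  markers <- vector("list", nT)
  for (t in seq_len(nT)) {
    mk <- detect_markers(hierarchies[[t]], raw_frames[[t]])
    if (nrow(mk))
      mk <- marker_feature_vectors(mk, raw_frames[[t]], enhanced_frames[[t]], spacing)
    markers[[t]] <- mk
  }
  links <- if (nT > 1) vector("list", nT - 1) else list()
  empty_ls <- function(dir, n) structure(
    list(direction = dir,
         links = data.frame(source = integer(), target = integer(),
                            cost = numeric(), dz = numeric(), dy = numeric(),
                            dx = numeric()),
         unmatched = seq_len(n)), class = "LinkageSet")
  if (nT > 1) for (t in seq_len(nT - 1)) {
    if (nrow(markers[[t]]) == 0 || nrow(markers[[t + 1]]) == 0) {
      links[[t]] <- list(forward = empty_ls("forward", nrow(markers[[t]])),
                         backward = empty_ls("backward", nrow(markers[[t + 1]])))
    } else {
      cm <- build_cost_matrix(markers[[t]], markers[[t + 1]], spacing,
                              max_travel_um, weights)
      links[[t]] <- link_best_match(cm)
    }
  }
  list(markers = markers, links = links)
}
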
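# Multilevel feature extraction: voxel motility, node-local flow patterns,
# branch and organelle morphology, and cross-level aggregation.
#
# Units: lengths in microns, times in seconds, angles in radians. The suffix
# `_12` marks quantities between frames t and t+1, `_01` between t-1 and t;
# accelerations need both and are absent (NA) on first/last frames.

angle_between <- function(a, b) {
  na <- row_norms(a); nb <- row_norms(b)
  dot <- rowSums(a * b)
  cosv <- ifelse(na * nb > 0, pmin(pmax(dot / (na * nb), -1), 1), NA_real_)
  acos(cosv)
}

# pivot node of each branch: skeleton node nearest the branch voxel centroid
branch_pivots <- function(hier) {
  sp3 <- spacing3_of(hier$spacing)
  d <- dim(hier$semantic)
  out <- list()
  nodes <- hier$nodes
  for (b in sort(unique(nodes$branch_id))) {
    vidx <- which(hier$branch_labels == b)
    cen <- colMeans(phys_coords(coords_from_index(vidx, d), sp3))
    ns <- nodes[nodes$branch_id == b, , drop = FALSE]
    nc <- phys_coords(as.matrix(ns[, c("z", "y", "x")]), sp3)
    k <- which.min(rowSums(sweep(nc, 2, cen)^2))
    out[[as.character(b)]] <- list(node_id = ns$node_id[k],
                                   coord = as.numeric(ns[k, c("z", "y", "x")]))
  }
  out
}

#' Voxel-level motility features
#'
#' Every mask voxel's position at the adjacent frames is obtained from the
#' interpolated flow; absolute, branch-pivot-relative (`rel_`), pivot
#' (`ref_`) and centre-of-mass-directionality (`com_`) kinematics are
#' derived from those positions. The branch pivot is the branch's skeleton
#' node nearest its voxel centroid, advanced by the same interpolated flow.
#'
#' @param hierarchies per-frame `LabelHierarchy` list.
#' @param raw_frames per-frame raw arrays.
#' @param enh_frames per-frame `EnhancedFrame`s.
#' @param tracking output of [track_markers()].
#' @param frame_interval seconds per frame.
#' @param max_travel_um flow search radius (microns).
#' @return data.frame, one row per (frame, mask voxel).
#' @export
voxel_motility_features <- function(hierarchies, raw_frames, enh_frames,
                                    tracking, frame_interval,
                                    max_travel_um = 1.0) {
  nT <- length(hierarchies)
  dt <- frame_interval
  out <- vector("list", nT)
  for (t in seq_len(nT)) {
    hier <- hierarchies[[t]]
    d <- dim(hier$semantic)
    sp3 <- spacing3_of(hier$spacing)
    vidx <- which(hier$semantic)
    if (!length(vidx)) next
    co <- coords_from_index(vidx, d)
    p_t <- phys_coords(co, sp3)
    nvox <- length(vidx)
    resp <- enh_frames[[t]]$response
    base <- data.frame(
      frame = t - 1L, z = co[, 1], y = co[, 2], x = co[, 3],
      node_id = hier$voxel_to_node[vidx],
      branch_id = hier$branch_labels[vidx],
      organelle_id = hier$organelle_labels[vidx],
      intensity_raw = raw_frames[[t]][vidx],
      intensity_enh = resp[vidx])
    has_fwd <- nT > 1 && t < nT
    has_bwd <- nT > 1 && t > 1
    pv <- branch_pivots(hier)
    pivot_t <- t(vapply(as.character(base$branch_id),
                        function(b) pv[[b]]$coord, numeric(3)))
    pivot_uni <- unique(pivot_t)
    pivot_key <- match(apply(pivot_t, 1, paste, collapse = ","),
                       apply(pivot_uni, 1, paste, collapse = ","))
    fwd_v <- bwd_v <- matrix(NA_real_, nvox, 3)
    if (has_fwd) {
      ff <- interpolate_flow(co, tracking$links[[t]]$forward,
                             tracking$markers[[t]], hier$spacing, max_travel_um)
      fwd_v <- ff$vectors_um
    }
    if (has_bwd) {
      fb <- interpolate_flow(co, tracking$links[[t - 1]]$backward,
                             tracking$markers[[t]], hier$spacing, max_travel_um)
      bwd_v <- fb$vectors_um
    }
    # the pivot advances with its branch's mean voxel flow: the centroid
    # velocity is far more stable than a point interpolation at one
    # coordinate, and agrees with it exactly for rigid translation
    branch_mean <- function(v) {
      out <- matrix(NA_real_, nrow(pivot_uni), 3)
      for (cmp in 1:3) {
        mu <- tapply(v[, cmp], base$branch_id, mean)
        bid_of_pivot <- vapply(seq_len(nrow(pivot_uni)), function(j)
          base$branch_id[pivot_key == j][1], numeric(1))
        out[, cmp] <- mu[as.character(bid_of_pivot)]
      }
      out
    }
    pfwd <- if (has_fwd) branch_mean(fwd_v) else matrix(NA_real_, nrow(pivot_uni), 3)
    pbwd <- if (has_bwd) branch_mean(bwd_v) else matrix(NA_real_, nrow(pivot_uni), 3)
    pivot_p <- phys_coords(pivot_t, sp3)
    # velocities (vectors, um/s)
    v12 <- fwd_v / dt
    v01 <- -bwd_v / dt
    base$lin_vel_mag_12 <- if (has_fwd) row_norms(v12) else NA_real_
    base$lin_vel_mag_01 <- if (has_bwd) row_norms(v01) else NA_real_
    # velocity components (um/s, zyx) so direction-aware statistics remain
    # possible downstream (a mean of magnitudes is noise-biased at low speed)
    if (has_fwd) {
      base$lin_vel_z_12 <- v12[, 1]; base$lin_vel_y_12 <- v12[, 2]
      base$lin_vel_x_12 <- v12[, 3]
    } else base$lin_vel_z_12 <- base$lin_vel_y_12 <- base$lin_vel_x_12 <- NA_real_
    base$lin_acc_mag <- if (has_fwd && has_bwd) row_norms(v12 - v01) / dt else NA_real_
    # pivot-relative positions
    q_t <- p_t - pivot_p
    if (has_fwd) {
      q_t1 <- (p_t + fwd_v) - (pivot_p + pfwd[pivot_key, , drop = FALSE])
      rel12 <- (q_t1 - q_t) / dt
      base$rel_lin_vel_mag_12 <- row_norms(rel12)
      base$rel_ang_vel_mag_12 <- angle_between(q_t, q_t1) / dt
    } else base$rel_lin_vel_mag_12 <- base$rel_ang_vel_mag_12 <- NA_real_
    if (has_bwd) {
      q_t0 <- (p_t + bwd_v) - (pivot_p + pbwd[pivot_key, , drop = FALSE])
      rel01 <- (q_t - q_t0) / dt
      base$rel_lin_vel_mag_01 <- row_norms(rel01)
      base$rel_ang_vel_mag_01 <- angle_between(q_t0, q_t) / dt
    } else base$rel_lin_vel_mag_01 <- base$rel_ang_vel_mag_01 <- NA_real_
    if (has_fwd && has_bwd) {
      base$rel_lin_acc_mag <- row_norms(rel12 - rel01) / dt
      base$rel_ang_acc_mag <- abs(base$rel_ang_vel_mag_12 -
                                    base$rel_ang_vel_mag_01) / dt
    } else base$rel_lin_acc_mag <- base$rel_ang_acc_mag <- NA_real_
    # pivot's own kinematics
    pv12 <- pfwd[pivot_key, , drop = FALSE] / dt
    pv01 <- -pbwd[pivot_key, , drop = FALSE] / dt
    base$ref_lin_vel_mag_12 <- if (has_fwd) row_norms(pv12) else NA_real_
    base$ref_lin_vel_mag_01 <- if (has_bwd) row_norms(pv01) else NA_real_
    base$ref_lin_acc_mag <- if (has_fwd && has_bwd)
      row_norms(pv12 - pv01) / dt else NA_real_
    # centre-of-mass directionality (per branch, broadcast to its voxels)
    wts <- pmax(base$intensity_raw, 0)
    if (sum(wts) == 0) wts <- rep(1, nvox)
    com <- colSums(p_t * wts) / sum(wts)
    dir_of <- function(vel) {
      u <- p_t - matrix(com, nvox, 3, byrow = TRUE)
      nu <- row_norms(u); nv <- row_norms(vel)
      cosv <- ifelse(nu * nv > 0, rowSums(u * vel) / (nu * nv), 0)
      stats::ave(cosv, base$branch_id, FUN = mean)
    }
    base$com_directionality_12 <- if (has_fwd) dir_of(v12) else NA_real_
    base$com_directionality_01 <- if (has_bwd) dir_of(v01) else NA_real_
    base$com_directionality_acceleration <- if (has_fwd && has_bwd)
      (base$com_directionality_12 - base$com_directionality_01) / dt else NA_real_
    out[[t]] <- base
  }
  do.call(rbind, out)
}

#' Node-level features
#'
#' Thickness is twice the node's distance-transform radius. Vergence is the
#' mean, over the node's assigned voxels, of the component of the voxel's
#' flow relative to the node centre's flow along the outward direction from
#' the node: positive = diverging, negative = converging flow.
#'
#' @param hier a `LabelHierarchy`.
#' @param flow_voxels optional matrix (mask voxels in scan order x 3, zyx
#'   microns) of per-voxel flow.
#' @param flow_nodes optional matrix (nodes x 3) of flow at node centres.
#' @return data.frame keyed by `node_id`.
#' @export
node_features <- function(hier, flow_voxels = NULL, flow_nodes = NULL) {
  nodes <- hier$nodes
  sp3 <- spacing3_of(hier$spacing)
  d <- dim(hier$semantic)
  vidx <- which(hier$semantic)
  nvox_per <- tabulate(hier$voxel_to_node[vidx], nbins = nrow(nodes))
  out <- data.frame(node_id = nodes$node_id, branch_id = nodes$branch_id,
                    organelle_id = nodes$organelle_id,
                    z = nodes$z, y = nodes$y, x = nodes$x,
                    radius_um = nodes$radius_um,
                    thickness_um = 2 * nodes$radius_um,
                    n_voxels = nvox_per,
                    is_junction = nodes$is_junction, is_tip = nodes$is_tip)
  if (!is.null(flow_voxels) && !is.null(flow_nodes)) {
    vergence <- rep(NA_real_, nrow(nodes))
    vassign <- hier$voxel_to_node[vidx]
    vp <- phys_coords(coords_from_index(vidx, d), sp3)
    np <- phys_coords(as.matrix(nodes[, c("z", "y", "x")]), sp3)
    for (k in seq_len(nrow(nodes))) {
      sel <- which(vassign == nodes$node_id[k])
      if (!length(sel)) next
      u <- vp[sel, , drop = FALSE] - matrix(np[k, ], length(sel), 3, byrow = TRUE)
      nu <- row_norms(u)
      ok <- nu > 0
      if (!any(ok)) { vergence[k] <- 0; next }
      relv <- flow_voxels[sel, , drop = FALSE] -
        matrix(flow_nodes[k, ], length(sel), 3, byrow = TRUE)
      vergence[k] <- mean(rowSums(relv[ok, , drop = FALSE] *
                                    (u[ok, , drop = FALSE] / nu[ok])))
    }
    out$vergence <- vergence
  }
  out
}

#' Branch-level morphology features
#'
#' Branch length is the physical length of the longest geodesic through the
#' branch's skeleton voxels (26-adjacency weighted by anisotropic step
#' length); tortuosity divides it by the end-to-end Euclidean distance
#' (1 for single-node branches); the aspect ratio is length over twice the
#' mean node radius.
#'
#' @param hier a `LabelHierarchy`.
#' @return data.frame keyed by `branch_id`.
#' @export
branch_features <- function(hier) {
  nodes <- hier$nodes
  sp3 <- spacing3_of(hier$spacing)
  d <- dim(hier$semantic)
  vox_vol <- if (is_flat(d)) sp3[2] * sp3[3] else prod(sp3)
  rows <- list()
  for (b in sort(unique(nodes$branch_id))) {
    ns <- nodes[nodes$branch_id == b, , drop = FALSE]
    nc <- as.matrix(ns[, c("z", "y", "x")])
    np <- phys_coords(nc, sp3)
    n <- nrow(ns)
    if (n == 1) {
      len <- 0; tort <- 1
    } else {
      # adjacency graph over the branch's skeleton voxels
      D2 <- outer(rowSums(np^2), rep(1, n)) + outer(rep(1, n), rowSums(np^2)) -
        2 * np %*% t(np)
      cheb <- pmax(abs(outer(nc[, 1], nc[, 1], `-`)),
                   abs(outer(nc[, 2], nc[, 2], `-`)),
                   abs(outer(nc[, 3], nc[, 3], `-`)))
      adj <- cheb == 1
      ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
      if (nrow(ij) == 0) { len <- 0; tort <- 1 }
      else {
        g <- igraph::graph_from_data_frame(
          data.frame(from = ij[, 1], to = ij[, 2],
                     weight = sqrt(pmax(D2[ij], 0))),
          directed = FALSE, vertices = data.frame(name = seq_len(n)))
        g <- igraph::mst(g)
        # double sweep for the longest geodesic
        d1 <- igraph::distances(g, v = 1)
        a <- which.max(ifelse(is.finite(d1), d1, -1))
        d2 <- igraph::distances(g, v = a)
        bb <- which.max(ifelse(is.finite(d2), d2, -1))
        len <- d2[bb]
        ee <- sqrt(sum((np[a, ] - np[bb, ])^2))
        tort <- if (ee > 0) len / ee else 1
      }
    }
    rad <- mean(ns$radius_um)
    nvox <- sum(hier$branch_labels == b)
    rows[[length(rows) + 1]] <- data.frame(
      branch_id = b, organelle_id = ns$organelle_id[1],
      branch_length = len, branch_radius = rad,
      branch_tortuosity = tort,
      branch_aspect_ratio = if (rad > 0) len / (2 * rad) else NA_real_,
      n_nodes = n, n_voxels = nvox, volume = nvox * vox_vol)
  }
  do.call(rbind, rows)
}

#' Organelle-level morphology features
#'
#' Volume (area in 2D) counts voxels times voxel volume; extent divides by
#' the bounding box; solidity by the rasterized convex hull (voxel centres
#' inside the hull of the organelle's voxels). Inertia-tensor eigenvalues
#' are those of the covariance of the voxel point cloud in physical
#' coordinates, sorted ascending; axis lengths use the ellipse-equivalent
#' convention `4 * sqrt(eigenvalue)`.
#'
#' @param hier a `LabelHierarchy`.
#' @return data.frame keyed by `organelle_id`.
#' @export
organelle_features <- function(hier) {
  sp3 <- spacing3_of(hier$spacing)
  d <- dim(hier$semantic)
  flat <- is_flat(d)
  vox_vol <- if (flat) sp3[2] * sp3[3] else prod(sp3)
  rows <- list()
  for (o in sort(setdiff(unique(as.vector(hier$organelle_labels)), 0L))) {
    vidx <- which(hier$organelle_labels == o)
    co <- coords_from_index(vidx, d)
    n <- length(vidx)
    bbox <- apply(co, 2, range)
    bbox_vox <- prod(bbox[2, ] - bbox[1, ] + 1)
    hull_vox <- hull_voxel_count(co)
    pp <- phys_coords(co, sp3)
    if (flat) pp <- pp[, 2:3, drop = FALSE]
    cc <- sweep(pp, 2, colMeans(pp))
    covm <- crossprod(cc) / n
    ev <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values)
    ev <- pmax(ev, 0)
    if (flat) {
      eig_min <- ev[1]; eig_mid <- NA_real_; eig_max <- ev[2]
    } else {
      eig_min <- ev[1]; eig_mid <- ev[2]; eig_max <- ev[3]
    }
    nb <- hier$nodes[hier$nodes$organelle_id == o, , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      organelle_id = o, n_voxels = n, volume = n * vox_vol,
      extent = n / bbox_vox,
      solidity = n / hull_vox,
      inertia_tensor_eig_sorted_min = eig_min,
      inertia_tensor_eig_sorted_mid = eig_mid,
      inertia_tensor_eig_sorted_max = eig_max,
      major_axis_length = 4 * sqrt(eig_max),
      minor_axis_length = 4 * sqrt(if (flat) ev[1] else max(ev[1], 0)),
      n_branches = length(unique(nb$branch_id)),
      n_nodes = nrow(nb))
  }
  do.call(rbind, rows)
}

#' Aggregate child-level features to a parent level
#'
#' For each parent and each requested (feature, statistic) pair a column
#' `{child_level}_{stat}_{feature}` is produced; empty child sets yield NA.
#' Nested aggregation works by feeding an aggregate table back in.
#'
#' @param child data.frame of child rows including the `parent_col`.
#' @param parent_col name of the lineage column (e.g. `"branch_id"`).
#' @param features character vector of child feature columns.
#' @param stats subset of `c("mean", "std", "min", "max", "median", "sum")`.
#' @param child_level label used as the column prefix (e.g. `"voxel"`).
#' @return data.frame with one row per parent id.
#' @export
aggregate_features <- function(child, parent_col, features,
                               stats = c("mean", "std", "min", "max",
                                         "median", "sum"),
                               child_level = "child") {
  fns <- list(mean = function(x) mean(x, na.rm = TRUE),
              std = function(x) stats::sd(x, na.rm = TRUE),
              min = function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE),
              max = function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE),
              median = function(x) stats::median(x, na.rm = TRUE),
              sum = function(x) sum(x, na.rm = TRUE))
  stopifnot(all(stats %in% names(fns)), parent_col %in% names(child))
  groups <- split(seq_len(nrow(child)), child[[parent_col]])
  ids <- names(groups)
  out <- data.frame(id = if (is.numeric(child[[parent_col]]))
    as.numeric(ids) else ids)
  names(out) <- parent_col
  for (f in features) {
    col_vals <- lapply(groups, function(ix) {
      v <- child[[f]][ix]
      v[!is.na(v)]
    })
    for (s in stats) {
      col <- paste0(child_level, "_", s, "_", f)
      out[[col]] <- vapply(col_vals, function(v)
        if (!length(v)) NA_real_ else fns[[s]](v), numeric(1))
    }
  }
  ord <- order(out[[parent_col]])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
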
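# Dense sub-voxel flow interpolated from marker linkages, track
# propagation, and voxel fate matching.

#' Interpolate flow vectors at arbitrary coordinates
#'
#' For each coordinate of interest (CoI), linked source markers within the
#' maximum travel distance contribute their displacement vectors with
#' weights `(1/(d_k + eps)) * (1/(c_k - c_min + eps))` (`eps = 1e-6`,
#' `c_min` the minimum cost among the contributing links), normalised to sum
#' to one: closer and better-matched linkages dominate. A CoI with no linked
#' marker in range gets the zero vector with support 0.
#'
#' @param cois n x 3 matrix of (possibly fractional) 0-based voxel
#'   coordinates (z, y, x).
#' @param linkset a `LinkageSet` for the frame pair (its direction decides
#'   whether the flow runs forward or backward in time).
#' @param markers marker table of the linkset's source frame.
#' @param spacing voxel spacing (microns).
#' @param max_travel_um search radius (microns).
#' @param eps_dist,eps_cost regularisers (microns / cost units) of the
#'   distance and cost preference terms.
#' @return a `FlowField`: list with `coords`, `vectors_um` (n x 3 zyx
#'   microns), `support` (contributing link count per CoI), `direction`.
#' @export
interpolate_flow <- function(cois, linkset, markers, spacing,
                             max_travel_um = 1.0, eps_dist = 1e-6,
                             eps_cost = 1e-6) {
  sp3 <- spacing3_of(spacing)
  cois <- rbind(cois)
  n <- nrow(cois)
  vec <- matrix(0, n, 3, dimnames = list(NULL, c("dz", "dy", "dx")))
  support <- integer(n)
  lk <- linkset$links
  if (nrow(lk) > 0) {
    src <- lk$source
    mco <- phys_coords(as.matrix(markers[src, c("z", "y", "x")]), sp3)
    lvec <- as.matrix(lk[, c("dz", "dy", "dx")])
    cost <- lk$cost
    qc <- phys_coords(cois, sp3)
    # distance matrix CoIs x links
    D2 <- outer(rowSums(qc^2), rep(1, nrow(mco))) +
      outer(rep(1, n), rowSums(mco^2)) - 2 * qc %*% t(mco)
    D <- sqrt(pmax(D2, 0))
    inrange <- D <= max_travel_um
    for (i in seq_len(n)) {
      sel <- which(inrange[i, ])
      if (!length(sel)) next
      cmin <- min(cost[sel])
      w <- (1 / (D[i, sel] + eps_dist)) * (1 / (cost[sel] - cmin + eps_cost))
      w <- w / sum(w)
      vec[i, ] <- colSums(w * lvec[sel, , drop = FALSE])
      support[i] <- length(sel)
    }
  }
  structure(list(coords = cois, vectors_um = vec, support = support,
                 direction = linkset$direction), class = "FlowField")
}

#' Propagate tracks through the interpolated flow
#'
#' Seeds (fractional 0-based voxel coordinates at frame `t0`) are advanced
#' frame by frame by their interpolated displacement (converted microns to
#' voxels per axis), accumulating sub-voxel positions; optionally also
#' backward from `t0` to the first frame. A track leaving the image bounds
#' is terminated and flagged.
#'
#' @param seeds n x 3 matrix of 0-based (z, y, x) seed coordinates.
#' @param tracking result of [track_markers()] (markers + links per pair).
#' @param dim3 frame dimensions (z, y, x).
#' @param spacing voxel spacing (microns).
#' @param t0 1-based seed frame.
#' @param backward also propagate backward to frame 1.
#' @param max_travel_um flow search radius (microns).
#' @param eps_dist,eps_cost flow-weight regularisers, see
#'   [interpolate_flow()].
#' @return data.frame: `track_id`, `frame`, `z`, `y`, `x` (fractional
#'   voxels), `zum`, `yum`, `xum`, `terminated`.
#' @export
propagate_tracks <- function(seeds, tracking, dim3, spacing, t0 = 1,
                             backward = FALSE, max_travel_um = 1.0,
                             eps_dist = 1e-6, eps_cost = 1e-6) {
  sp3 <- spacing3_of(spacing)
  seeds <- rbind(seeds)
  nT <- length(tracking$markers)
  n <- nrow(seeds)
  rows <- list()
  emit <- function(tid, fr, co, term) {
    data.frame(track_id = tid, frame = fr, z = co[1], y = co[2], x = co[3],
               zum = co[1] * sp3[1], yum = co[2] * sp3[2], xum = co[3] * sp3[3],
               terminated = term)
  }
  inb <- function(co) all(co >= -0.5 & co <= dim3 - 0.5)
  for (i in seq_len(n)) {
    co <- as.numeric(seeds[i, ])
    rows[[length(rows) + 1]] <- emit(i, t0, co, FALSE)
    # forward
    cur <- co; alive <- inb(cur)
    if (t0 < nT) for (t in t0:(nT - 1)) {
      if (!alive) break
      ff <- interpolate_flow(cur, tracking$links[[t]]$forward,
                             tracking$markers[[t]], spacing, max_travel_um,
                             eps_dist, eps_cost)
      cur <- cur + ff$vectors_um[1, ] / sp3
      alive <- inb(cur)
      rows[[length(rows) + 1]] <- emit(i, t + 1, cur, !alive)
    }
    if (backward && t0 > 1) {
      cur <- co; alive <- inb(cur)
      for (t in (t0 - 1):1) {
        if (!alive) break
        ff <- interpolate_flow(cur, tracking$links[[t]]$backward,
                               tracking$markers[[t + 1]], spacing, max_travel_um,
                               eps_dist, eps_cost)
        cur <- cur + ff$vectors_um[1, ] / sp3
        alive <- inb(cur)
        rows[[length(rows) + 1]] <- emit(i, t, cur, !alive)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Match voxels between adjacent frames (voxel fate)
#'
#' Each mask voxel at frame t is displaced by its interpolated forward flow
#' and rounded; if it lands inside the frame-t+1 mask it is matched to that
#' voxel, otherwise to the nearest frame-t+1 mask voxel within one voxel of
#' the landing point (ties to the lowest index), otherwise flagged
#' unmatched.
#'
#' @param hier_t,hier_t1 `LabelHierarchy` of frames t and t+1.
#' @param flow_t `FlowField` evaluated at frame t's mask voxels (in mask
#'   scan order).
#' @return data.frame: `voxel_t` (1-based linear index at t), `voxel_t1`
#'   (1-based linear index at t+1, or `NA`), plus the matched voxel's
#'   `organelle_id`, `branch_id`, `node_id` at t+1.
#' @export
match_voxels <- function(hier_t, hier_t1, flow_t) {
  d <- dim(hier_t$semantic)
  sp3 <- spacing3_of(hier_t$spacing)
  vidx <- which(hier_t$semantic)
  stopifnot(nrow(flow_t$coords) == length(vidx))
  landing <- flow_t$coords + sweep(flow_t$vectors_um, 2, sp3, `/`)
  rounded <- round(landing)
  target <- rep(NA_integer_, length(vidx))
  m1 <- hier_t1$semantic
  offs <- rbind(c(0, 0, 0), as.matrix(neighbor_offsets(d)))
  for (i in seq_along(vidx)) {
    rc <- rounded[i, ]
    best <- NA_integer_; bestd <- Inf
    for (k in seq_len(nrow(offs))) {
      cc <- rc + offs[k, ]
      if (any(cc < 0) || any(cc >= d)) next
      j <- index_from_coords(cc, d)
      if (!m1[j]) next
      dd <- sum(((cc - landing[i, ]) * sp3)^2)
      if (k == 1) { best <- j; break }   # direct hit
      if (dd < bestd - 1e-12 || (abs(dd - bestd) <= 1e-12 && (is.na(best) || j < best))) {
        best <- j; bestd <- dd
      }
    }
    target[i] <- best
  }
  nid <- ifelse(is.na(target), NA_integer_, hier_t1$voxel_to_node[pmax(target, 1)])
  data.frame(
    voxel_t = vidx, voxel_t1 = target,
    organelle_id = ifelse(is.na(target), NA_integer_,
                          hier_t1$organelle_labels[pmax(target, 1)]),
    branch_id = ifelse(is.na(target), NA_integer_,
                       hier_t1$branch_labels[pmax(target, 1)]),
    node_id = nid)
}
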
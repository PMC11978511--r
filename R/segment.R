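# Hierarchical segmentation: threshold -> organelles -> skeleton ->
# branches -> nodes -> voxel assignment.

hist_256 <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) stop("constant response: no segmentable structure")
  edges <- seq(rng[1], rng[2], length.out = 257L)
  counts <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE), 256L),
                     nbins = 256L)
  list(counts = counts, edges = edges,
       mids = (edges[-1] + edges[-257]) / 2)
}

otsu_threshold_hist <- function(h) {
  w <- h$counts / sum(h$counts)
  mu <- h$mids
  best <- -Inf; best_k <- 1L
  cw <- cumsum(w); cm <- cumsum(w * mu)
  mt <- cm[256]
  for (k in 1:255) {
    w0 <- cw[k]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- cm[k] / w0; m1 <- (mt - cm[k]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best + 1e-15) { best <- v; best_k <- k }
  }
  h$edges[best_k + 1L]
}

triangle_threshold_hist <- function(h) {
  cnt <- h$counts
  nz <- which(cnt > 0)
  p <- which.max(cnt)                       # first peak
  lo <- nz[1]; hi <- nz[length(nz)]
  # side with the longer tail from the peak
  if ((hi - p) >= (p - lo)) { a <- p; b <- hi } else { a <- p; b <- lo }
  if (a == b) return(h$mids[p])
  ks <- if (b > a) a:b else b:a
  # distance from (k, cnt[k]) to the line (a, cnt[a]) -- (b, cnt[b])
  dxl <- b - a; dyl <- cnt[b] - cnt[a]
  dist <- abs(dyl * (ks - a) - dxl * (cnt[ks] - cnt[a])) / sqrt(dxl^2 + dyl^2)
  kbest <- ks[which.max(dist)]
  h$edges[kbest + 1L]
}

#' Minimum-of-Otsu-and-triangle threshold on the enhanced response
#'
#' Both classic thresholds are computed on a 256-bin histogram of the
#' strictly positive response values; the minimum of the two is returned,
#' biasing segmentation toward sensitivity so dim structures survive.
#'
#' @param enhanced an `EnhancedFrame` (or a numeric response array).
#' @return the threshold value.
#' @export
minotri_threshold <- function(enhanced) {
  resp <- if (inherits(enhanced, "EnhancedFrame")) enhanced$response else enhanced
  v <- resp[resp > 0]
  if (length(unique(v)) < 2)
    stop("response has < 2 distinct nonzero values: no segmentable structure")
  h <- hist_256(v)
  min(otsu_threshold_hist(h), triangle_threshold_hist(h))
}

#' Otsu threshold on the enhanced response
#'
#' Otsu's between-class-variance threshold on a 256-bin histogram of the
#' strictly positive response values; the default automatic threshold for
#' semantic segmentation.
#'
#' @param enhanced an `EnhancedFrame` (or a numeric response array).
#' @return the threshold value.
#' @export
otsu_threshold <- function(enhanced) {
  resp <- if (inherits(enhanced, "EnhancedFrame")) enhanced$response else enhanced
  v <- resp[resp > 0]
  if (length(unique(v)) < 2)
    stop("response has < 2 distinct nonzero values: no segmentable structure")
  otsu_threshold_hist(hist_256(v))
}

#' Semantic mask from the enhanced response
#'
#' Thresholds the response and removes small connected components. With the
#' default `min_size_um = 0` only single isolated voxels are discarded.
#'
#' @param enhanced `EnhancedFrame` or response array.
#' @param threshold threshold value (e.g. from [minotri_threshold()]).
#' @param min_size_um minimum component size in square (2D) / cubic (3D)
#'   microns; 0 keeps everything except single-voxel specks.
#' @param spacing voxel spacing in microns.
#' @return logical (z, y, x) mask array.
#' @export
semantic_mask <- function(enhanced, threshold, min_size_um = 0, spacing) {
  resp <- if (inherits(enhanced, "EnhancedFrame")) enhanced$response else enhanced
  if (!is.finite(threshold)) stop("threshold must be finite")
  d <- dim(resp)
  mask <- resp > threshold
  if (!any(mask)) {
    warning("empty semantic mask: threshold above all response values")
    return(array(FALSE, dim = d))
  }
  sp3 <- spacing3_of(spacing)
  vox_vol <- if (is_flat(d)) sp3[2] * sp3[3] else prod(sp3)
  min_vox <- if (min_size_um > 0) min_size_um / vox_vol else 2
  lab <- cc_label_full(as.vector(mask), d)
  sizes <- tabulate(lab)
  drop <- which(sizes < min_vox)
  if (length(drop)) mask[array(lab %in% drop, dim = d)] <- FALSE
  if (!any(mask)) warning("empty semantic mask after small-object removal")
  mask
}

#' Label organelles by full-connectivity connected components
#'
#' 8-connectivity in 2D, 26-connectivity in 3D; labels 1..N are assigned
#' deterministically in array scan order.
#'
#' @param mask logical (z, y, x) array.
#' @return integer label array (0 = background).
#' @export
label_organelles <- function(mask) {
  d <- dim(mask)
  array(cc_label_full(as.vector(mask), d), dim = d)
}

#' Anisotropic Euclidean distance transform
#'
#' Exact distance (in microns) from each foreground voxel to the nearest
#' background voxel centre, honouring per-axis spacing.
#'
#' @param mask logical (z, y, x) array.
#' @param spacing voxel spacing in microns.
#' @return numeric array of distances in microns.
#' @export
distance_transform <- function(mask, spacing) {
  d <- dim(mask)
  sp3 <- spacing3_of(spacing)
  array(edt_aniso(as.vector(mask), d, sp3), dim = d)
}

#' Topology-preserving skeletonization
#'
#' Medial-axis curve thinning: border voxels are removed in increasing
#' distance-transform order whenever removal preserves topology (simple
#' points), keeping curve endpoints, until stable. Every connected object
#' retains at least one voxel; single-voxel objects are their own skeleton.
#'
#' @param mask logical (z, y, x) array.
#' @param distance_um distance transform of `mask` (used to centre the
#'   skeleton); computed if missing.
#' @param spacing voxel spacing in microns (only needed to compute the
#'   distance transform).
#' @return logical skeleton array.
#' @export
skeletonize <- function(mask, distance_um = NULL, spacing = NULL) {
  d <- dim(mask)
  if (is.null(distance_um)) {
    if (is.null(spacing)) stop("need distance_um or spacing")
    distance_um <- distance_transform(mask, spacing)
  }
  array(thin_skeleton(as.vector(mask), d, as.vector(distance_um)), dim = d)
}

#' Decompose a skeleton into junctions, tips and labeled branches
#'
#' Junction voxels have more than two skeleton neighbours (full
#' connectivity); tips exactly one. Branches are the connected components of
#' the skeleton with junction voxels removed, labeled 1..B in scan order;
#' every junction voxel is then attached to the adjacent branch with the
#' lowest label so that all skeleton voxels carry a branch label. Skeleton
#' components consisting solely of junction voxels become branches of their
#' own.
#'
#' @param skeleton logical (z, y, x) array.
#' @return list with logical arrays `junction`, `tip` and the integer
#'   `branch_labels` array (0 off-skeleton), plus `n_branches`.
#' @export
label_branches <- function(skeleton) {
  d <- dim(skeleton)
  nb <- array(neighbor_count_full(as.vector(skeleton), d), dim = d)
  junction <- skeleton & nb > 2L
  tip <- skeleton & nb == 1L
  core <- skeleton & !junction
  blab <- array(cc_label_full(as.vector(core), d), dim = d)
  nb_branches <- max(blab)
  # attach junction voxels to the adjacent branch with the lowest label;
  # repeat so junction voxels adjacent only to other junctions resolve too
  jidx <- which(junction)
  if (length(jidx)) {
    offs <- neighbor_offsets(d)
    repeat {
      un <- jidx[blab[jidx] == 0L]
      if (!length(un)) break
      assigned <- FALSE
      for (i in un) {
        nbr <- neighbor_indices(i, d, offs)
        cand <- blab[nbr]
        cand <- cand[cand > 0L]
        if (length(cand)) { blab[i] <- min(cand); assigned <- TRUE }
      }
      if (!assigned) break
    }
    # skeleton components made of junction voxels only: new labels per cluster
    un <- jidx[blab[jidx] == 0L]
    if (length(un)) {
      left <- array(FALSE, dim = d); left[un] <- TRUE
      extra <- array(cc_label_full(as.vector(left), d), dim = d)
      blab[un] <- nb_branches + extra[un]
      nb_branches <- nb_branches + max(extra)
    }
  }
  list(junction = junction, tip = tip, branch_labels = blab,
       n_branches = max(nb_branches, max(blab)))
}

# cached full-connectivity neighbour linear offsets (may cross array edges;
# neighbor_indices() filters)
neighbor_offsets <- function(d) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  g
}

neighbor_indices <- function(i, d, offs) {
  cz <- (i - 1L) %% d[1]
  r <- (i - 1L) %/% d[1]
  cy <- r %% d[2]; cx <- r %/% d[2]
  z <- cz + offs$dz; y <- cy + offs$dy; x <- cx + offs$dx
  ok <- z >= 0 & z < d[1] & y >= 0 & y < d[2] & x >= 0 & x < d[3]
  as.integer(z[ok] + d[1] * (y[ok] + d[2] * x[ok]) + 1L)
}

#' Assign every mask voxel to its nearest skeleton node
#'
#' Nearest is measured in physical (micron) distance, restricted to nodes of
#' the voxel's own organelle; ties go to the lowest node index.
#'
#' @param mask logical array.
#' @param organelle_labels integer organelle label array.
#' @param nodes node table (`node_id`, `z`, `y`, `x`, `organelle_id`).
#' @param spacing voxel spacing in microns.
#' @return integer array mapping voxels to node ids (0 = background).
#' @export
assign_voxels_to_nodes <- function(mask, organelle_labels, nodes, spacing) {
  d <- dim(mask)
  sp3 <- spacing3_of(spacing)
  out <- array(0L, dim = d)
  if (!any(mask)) return(out)
  for (org in sort(unique(nodes$organelle_id))) {
    nsub <- nodes[nodes$organelle_id == org, , drop = FALSE]
    nsub <- nsub[order(nsub$node_id), , drop = FALSE]
    vidx <- which(organelle_labels == org)
    stopifnot(nrow(nsub) > 0)
    vc <- phys_coords(coords_from_index(vidx, d), sp3)
    nc <- phys_coords(as.matrix(nsub[, c("z", "y", "x")]), sp3)
    # chunk to bound memory
    step <- max(1L, as.integer(2e6 / max(1L, nrow(nsub))))
    for (s in seq(1L, length(vidx), by = step)) {
      e <- min(s + step - 1L, length(vidx))
      D <- outer(rowSums(vc[s:e, , drop = FALSE]^2), rep(1, nrow(nc))) +
        outer(rep(1, e - s + 1L), rowSums(nc^2)) -
        2 * vc[s:e, , drop = FALSE] %*% t(nc)
      pick <- max.col(-round(D, 12), ties.method = "first")
      out[vidx[s:e]] <- nsub$node_id[pick]
    }
  }
  out
}

#' Full hierarchical segmentation of one frame
#'
#' Runs threshold, instance labeling, distance transform, skeletonization,
#' branch decomposition and voxel-to-node assignment, returning the complete
#' label hierarchy for the frame.
#'
#' @param enhanced an `EnhancedFrame`.
#' @param spacing voxel spacing in microns.
#' @param min_size_um minimum organelle size passed to [semantic_mask()].
#' @param threshold optional externally supplied threshold.
#' @param threshold_method automatic threshold when `threshold` is NULL:
#'   `"otsu"` (default; Otsu on the nonzero response) or `"minotri"` (the
#'   more sensitive min-of-Otsu-and-triangle variant, which keeps dim
#'   structures at the price of wider masks).
#' @return a `LabelHierarchy`: semantic mask, organelle/branch/node label
#'   arrays, node table (coordinates 0-based, radii in microns), voxel->node
#'   assignment and the distance transform.
#' @export
segment_frame <- function(enhanced, spacing, min_size_um = 0, threshold = NULL,
                          threshold_method = c("otsu", "minotri")) {
  threshold_method <- match.arg(threshold_method)
  resp <- enhanced$response
  d <- dim(resp)
  empty <- function() {
    structure(list(
      semantic = array(FALSE, d), organelle_labels = array(0L, d),
      branch_labels = array(0L, d), voxel_to_node = array(0L, d),
      nodes = data.frame(node_id = integer(), z = integer(), y = integer(),
                         x = integer(), radius_um = numeric(),
                         branch_id = integer(), organelle_id = integer(),
                         is_junction = logical(), is_tip = logical()),
      distance_um = array(0, d), spacing = spacing, threshold = NA_real_),
      class = "LabelHierarchy")
  }
  thr <- threshold
  if (is.null(thr)) {
    thr <- tryCatch(
      if (threshold_method == "minotri") minotri_threshold(enhanced)
      else otsu_threshold(enhanced),
      error = function(e) NA_real_)
    if (is.na(thr)) { warning("no segmentable structure in frame"); return(empty()) }
  }
  mask <- semantic_mask(enhanced, thr, min_size_um, spacing)
  if (!any(mask)) { h <- empty(); h$threshold <- thr; return(h) }
  org <- label_organelles(mask)
  dist_um <- distance_transform(mask, spacing)
  skel <- skeletonize(mask, dist_um)
  br <- label_branches(skel)
  sidx <- which(skel)
  co <- coords_from_index(sidx, d)
  nodes <- data.frame(
    node_id = seq_along(sidx),
    z = co[, 1], y = co[, 2], x = co[, 3],
    radius_um = dist_um[sidx],
    branch_id = br$branch_labels[sidx],
    organelle_id = org[sidx],
    is_junction = br$junction[sidx],
    is_tip = br$tip[sidx])
  v2n <- assign_voxels_to_nodes(mask, org, nodes, spacing)
  blab_full <- array(0L, d)
  blab_full[mask] <- nodes$branch_id[v2n[mask]]
  structure(list(
    semantic = mask, organelle_labels = org, branch_labels = blab_full,
    voxel_to_node = v2n, nodes = nodes, distance_um = dist_um,
    spacing = spacing, threshold = thr, skeleton = skel),
    class = "LabelHierarchy")
}

#' @export
print.LabelHierarchy <- function(x, ...) {
  cat("LabelHierarchy:", sum(x$semantic), "mask voxels,",
      max(x$organelle_labels), "organelles,",
      if (nrow(x$nodes)) max(x$nodes$branch_id) else 0L, "branches,",
      nrow(x$nodes), "nodes\n")
  invisible(x)
}
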
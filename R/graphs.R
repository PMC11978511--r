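# Skeleton graphs (junctions/tips as nodes, branches as edges), topology
# metrics, and power-of-two multi-mesh adjacency construction.

#' Build the junction-edge skeleton graph of an organelle (or all)
#'
#' Junction voxel clusters are contracted to single graph nodes; tips are
#' nodes; every branch becomes one edge between the graph nodes at its ends
#' (a self-loop when both ends meet the same junction cluster). Isolated
#' cyclic skeletons with neither junction nor tip become one node carrying
#' one self-loop; isolated single voxels become an edgeless node. The graph
#' is a multigraph: parallel edges and self-loops are kept, since collapsing
#' them would corrupt cycle counts.
#'
#' @param hier a `LabelHierarchy`.
#' @param organelle_id restrict to one organelle (default all).
#' @return a `SkeletonGraph`: list with the igraph object `g`, a node table
#'   (`graph_node_id`, `kind`, coords, `organelle_id`) and an edge table
#'   (`branch_id`, endpoints).
#' @export
build_skeleton_graph <- function(hier, organelle_id = NULL) {
  nodes <- hier$nodes
  if (!is.null(organelle_id))
    nodes <- nodes[nodes$organelle_id %in% organelle_id, , drop = FALSE]
  d <- dim(hier$semantic)
  if (nrow(nodes) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(g = g, nodes = data.frame(), edges = data.frame()),
                     class = "SkeletonGraph"))
  }
  skel_idx <- index_from_coords(as.matrix(nodes[, c("z", "y", "x")]), d)
  in_skel <- array(FALSE, d); in_skel[skel_idx] <- TRUE
  node_at <- array(0L, d); node_at[skel_idx] <- seq_len(nrow(nodes))

  # junction clusters
  jmask <- array(FALSE, d)
  jmask[skel_idx[nodes$is_junction]] <- TRUE
  jclust <- array(cc_label_full(as.vector(jmask), d), dim = d)
  n_j <- max(jclust)

  # graph nodes: junction clusters 1..n_j, then tips
  tip_rows <- which(nodes$is_tip)
  gn <- data.frame(
    graph_node_id = seq_len(n_j + length(tip_rows)),
    kind = c(rep("junction", n_j), rep("tip", length(tip_rows))))
  coords <- matrix(NA_real_, nrow(gn), 3)
  orgs <- integer(nrow(gn))
  if (n_j > 0) for (j in seq_len(n_j)) {
    vi <- which(jclust == j)
    co <- coords_from_index(vi, d)
    coords[j, ] <- colMeans(co)
    orgs[j] <- nodes$organelle_id[node_at[vi[1]]]
  }
  if (length(tip_rows)) {
    coords[n_j + seq_along(tip_rows), ] <-
      as.matrix(nodes[tip_rows, c("z", "y", "x")])
    orgs[n_j + seq_along(tip_rows)] <- nodes$organelle_id[tip_rows]
  }
  gn$z <- coords[, 1]; gn$y <- coords[, 2]; gn$x <- coords[, 3]
  gn$organelle_id <- orgs
  tip_gnode <- integer(nrow(nodes))
  tip_gnode[tip_rows] <- n_j + seq_along(tip_rows)

  offs <- neighbor_offsets(d)
  edges <- list()
  extra_nodes <- list()
  for (b in sort(unique(nodes$branch_id))) {
    brows <- which(nodes$branch_id == b & !nodes$is_junction)
    if (!length(brows)) {
      # all-junction branch: the cluster is a node; no edge
      next
    }
    bidx <- skel_idx[brows]
    bset <- array(FALSE, d); bset[bidx] <- TRUE
    internal_deg <- vapply(seq_along(bidx), function(k)
      sum(bset[neighbor_indices(bidx[k], d, offs)]), 0)
    ends <- which(internal_deg <= 1L)    # terminal voxels of the branch path
    # each terminal attaches to a tip node or its adjacent junction clusters
    att_per_end <- lapply(ends, function(k) {
      nrow_k <- brows[k]
      if (nodes$is_tip[nrow_k]) return(tip_gnode[nrow_k])
      jc <- jclust[neighbor_indices(bidx[k], d, offs)]
      sort(unique(jc[jc > 0]))
    })
    attach <- if (length(ends) >= 2) {
      unlist(lapply(att_per_end, function(a) if (length(a)) a[1] else integer()))
    } else unlist(att_per_end)
    if (length(attach) >= 2) {
      e <- sort(attach[1:2])
    } else if (length(attach) == 1) {
      e <- c(attach[1], attach[1])      # loop anchored at one junction
    } else {
      # isolated: cycle -> self-loop node; single voxel/path without tips
      co <- coords_from_index(bidx, d)
      ord <- order(co[, 1], co[, 2], co[, 3])
      nid <- nrow(gn) + length(extra_nodes) + 1L
      extra_nodes[[length(extra_nodes) + 1]] <- data.frame(
        graph_node_id = nid, kind = "isolated",
        z = co[ord[1], 1], y = co[ord[1], 2], x = co[ord[1], 3],
        organelle_id = nodes$organelle_id[brows[1]])
      is_cycle <- length(bidx) > 1 && all(internal_deg >= 2)
      if (is_cycle) e <- c(nid, nid) else e <- NULL
    }
    if (!is.null(e))
      edges[[length(edges) + 1]] <- data.frame(branch_id = b,
                                               from = e[1], to = e[2])
  }
  if (length(extra_nodes)) gn <- rbind(gn, do.call(rbind, extra_nodes))
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(branch_id = integer(), from = integer(), to = integer())
  g <- igraph::graph_from_data_frame(
    d = ed[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = gn$graph_node_id))
  structure(list(g = g, nodes = gn, edges = ed), class = "SkeletonGraph")
}

#' Topology metrics of a skeleton graph
#'
#' Per node: degree (self-loops count twice) and betweenness centrality on
#' the underlying simple graph, normalised by `2 / ((n-1)(n-2))` (0 when
#' n < 3). Per graph: mean degree, the degree distribution, mean
#' betweenness, the cyclomatic number `E - N + C`, and the normalised
#' cyclomatic number `(E - N + C) / N`.
#'
#' @param sg a `SkeletonGraph`.
#' @return list with `per_node` data.frame and `per_graph` list.
#' @export
topology_metrics <- function(sg) {
  g <- sg$g
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  deg <- igraph::degree(g)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  btw_raw <- igraph::betweenness(gs, directed = FALSE)
  btw <- if (n < 3) rep(0, n) else btw_raw * 2 / ((n - 1) * (n - 2))
  E <- igraph::ecount(g)
  C <- igraph::components(g)$no
  cyc <- E - n + C
  list(per_node = data.frame(graph_node_id = sg$nodes$graph_node_id,
                             kind = sg$nodes$kind,
                             degree = as.integer(deg),
                             betweenness = as.numeric(btw)),
       per_graph = list(n_nodes = n, n_edges = E, n_components = C,
                        mean_degree = mean(deg),
                        degree_distribution = table(deg),
                        mean_betweenness = mean(btw),
                        cyclomatic = cyc,
                        normalized_cyclomatic = cyc / n))
}

#' Power-of-two multi-mesh of one organelle's skeleton
#'
#' Skeleton voxels are ordered by a depth-first traversal from the tip with
#' the lexicographically smallest coordinate (children visited in
#' lexicographic order; the smallest-coordinate node is the fallback root
#' when no tip exists). Level l connects traversal indices `k*2^l` and
#' `(k+1)*2^l`; level 0 therefore contains every consecutive pair, and a
#' path of N ordered nodes has `floor(log2(N-1)) + 1` levels. Per-node
#' feature vectors aggregate (mean) raw/enhanced intensity and voxel
#' motility over the node's assigned voxels plus the node radius, z-scored
#' per organelle.
#'
#' @param hier a `LabelHierarchy`.
#' @param organelle_id the organelle to mesh.
#' @param voxel_features optional voxel feature table (from
#'   [voxel_motility_features()]) for node feature aggregation.
#' @return a `MultiMesh`: list with `order` (node ids in traversal order),
#'   `levels` (list of edge matrices, level l at index l+1), `edge_list`
#'   (level, i, j as 0-based traversal indices), `adjacency` (dense 0/1
#'   matrix over ordered nodes), `node_features`.
#' @export
build_multimesh <- function(hier, organelle_id, voxel_features = NULL) {
  nodes <- hier$nodes[hier$nodes$organelle_id == organelle_id, , drop = FALSE]
  stopifnot(nrow(nodes) >= 1)
  d <- dim(hier$semantic)
  co <- as.matrix(nodes[, c("z", "y", "x")])
  n <- nrow(nodes)
  lex <- order(co[, 1], co[, 2], co[, 3])
  # skeleton adjacency among these nodes
  idx <- index_from_coords(co, d)
  node_at <- array(0L, d); node_at[idx] <- seq_len(n)
  offs <- neighbor_offsets(d)
  adj <- vector("list", n)
  for (k in seq_len(n)) {
    nbr <- node_at[neighbor_indices(idx[k], d, offs)]
    nbr <- nbr[nbr > 0]
    adj[[k]] <- nbr[order(co[nbr, 1], co[nbr, 2], co[nbr, 3])]
  }
  tips <- which(vapply(adj, length, 1L) == 1L)
  root <- if (length(tips)) tips[order(co[tips, 1], co[tips, 2], co[tips, 3])[1]]
  else lex[1]
  # iterative DFS, children in lexicographic order
  visited <- logical(n)
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (visited[cur]) next
    visited[cur] <- TRUE
    ord <- c(ord, cur)
    ch <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(ch)) stack <- c(stack, rev(ch))   # visit smallest first
  }
  # disconnected leftovers (should not occur within one organelle)
  if (any(!visited)) ord <- c(ord, which(!visited))
  N <- length(ord)
  levels <- list()
  if (N >= 2) {
    n_lev <- floor(log2(N - 1)) + 1
    for (l in seq_len(n_lev) - 1L) {
      stride <- 2^l
      ks <- seq(0, N - 1 - stride, by = stride)
      levels[[l + 1]] <- cbind(i = ks, j = ks + stride)
    }
  }
  edge_list <- if (length(levels)) do.call(rbind, lapply(seq_along(levels),
    function(li) cbind(level = li - 1L, levels[[li]]))) else
      matrix(integer(), 0, 3, dimnames = list(NULL, c("level", "i", "j")))
  A <- matrix(0L, N, N)
  if (nrow(edge_list)) {
    A[edge_list[, c("i", "j")] + 1L] <- 1L
    A[edge_list[, c("j", "i")] + 1L] <- 1L
  }
  nf <- data.frame(traversal_index = seq_len(N) - 1L,
                   node_id = nodes$node_id[ord],
                   radius_um = nodes$radius_um[ord])
  if (!is.null(voxel_features)) {
    feats <- intersect(c("intensity_raw", "intensity_enh",
                         "lin_vel_mag_12", "lin_vel_mag_01", "lin_acc_mag",
                         "rel_lin_vel_mag_12", "rel_ang_vel_mag_12"),
                       names(voxel_features))
    agg <- aggregate_features(
      voxel_features[voxel_features$organelle_id == organelle_id, , drop = FALSE],
      "node_id", feats, stats = "mean", child_level = "voxel")
    nf <- merge(nf, agg, by = "node_id", all.x = TRUE, sort = FALSE)
    nf <- nf[order(nf$traversal_index), , drop = FALSE]
  }
  # z-score numeric feature columns per organelle
  zcols <- setdiff(names(nf), c("traversal_index", "node_id"))
  for (cn in zcols) {
    v <- nf[[cn]]
    s <- stats::sd(v, na.rm = TRUE)
    nf[[cn]] <- if (is.finite(s) && s > 0) (v - mean(v, na.rm = TRUE)) / s else v * 0
  }
  structure(list(order = nodes$node_id[ord], levels = levels,
                 edge_list = edge_list, adjacency = A, node_features = nf),
            class = "MultiMesh")
}
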
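sg_from_edges <- function(edges, n) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  structure(list(g = g,
                 nodes = data.frame(graph_node_id = seq_len(n),
                                    kind = "junction"),
                 edges = data.frame(branch_id = seq_len(nrow(edges)),
                                    from = edges[, 1], to = edges[, 2])),
            class = "SkeletonGraph")
}

test_that("cyclomatic numbers and betweenness match closed forms", {
  path <- sg_from_edges(cbind(1:4, 2:5), 5)
  tm <- topology_metrics(path)
  expect_equal(tm$per_graph$cyclomatic, 0)
  cyc <- sg_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4)
  expect_equal(topology_metrics(cyc)$per_graph$cyclomatic, 1)
  star <- sg_from_edges(cbind(1, 2:5), 5)
  tms <- topology_metrics(star)
  expect_equal(tms$per_node$betweenness[1], 1.0)
  expect_equal(tms$per_node$betweenness[2:5], rep(0, 4))
  expect_equal(tms$per_node$degree[1], 4L)
})

test_that("betweenness equals the exhaustive path-count oracle", {
  set.seed(41)
  for (rep in 1:4) {
    n <- sample(6:12, 1)
    ne <- sample(n:(2 * n), 1)
    edges <- cbind(sample(n, ne, TRUE), sample(n, ne, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- unique(t(apply(edges, 1, sort)))
    if (nrow(edges) < 2) next
    sg <- sg_from_edges(edges, n)
    tm <- topology_metrics(sg)
    expected <- oracle_betweenness(edges, n) * 2 / ((n - 1) * (n - 2))
    expect_equal(tm$per_node$betweenness, expected, tolerance = 1e-9)
  }
})

test_that("skeleton graphs contract junctions and keep loops", {
  # straight tube: two tip nodes, one edge
  h <- hierarchy_from_mask(shape_tube2d())
  sg <- build_skeleton_graph(h)
  expect_equal(igraph::vcount(sg$g), 2)
  expect_equal(igraph::ecount(sg$g), 1)

  # plus sign: 1 junction + 4 tips, 4 edges, junction degree 4
  hp <- hierarchy_from_mask(shape_plus())
  sgp <- build_skeleton_graph(hp)
  expect_equal(igraph::vcount(sgp$g), 5)
  expect_equal(igraph::ecount(sgp$g), 4)
  tmp <- topology_metrics(sgp)
  expect_equal(sort(tmp$per_node$degree), c(1, 1, 1, 1, 4))
  expect_equal(sum(igraph::degree(sgp$g)), 2 * igraph::ecount(sgp$g))

  # closed ring: one node with a self-loop, cyclomatic 1
  hr <- hierarchy_from_mask(shape_ring())
  sgr <- build_skeleton_graph(hr)
  expect_equal(igraph::vcount(sgr$g), 1)
  expect_equal(igraph::ecount(sgr$g), 1)
  expect_equal(topology_metrics(sgr)$per_graph$cyclomatic, 1)
})

test_that("Euler identity holds against a spanning-tree cycle count", {
  for (shape in list(shape_plus(), shape_ring(), shape_y())) {
    h <- hierarchy_from_mask(shape)
    sg <- build_skeleton_graph(h)
    tm <- topology_metrics(sg)
    g <- sg$g
    # independent cycles = E - |spanning forest edges|
    forest_edges <- igraph::vcount(g) - igraph::components(g)$no
    expect_equal(tm$per_graph$cyclomatic, igraph::ecount(g) - forest_edges)
  }
})

test_that("hexagonal tubular lattice has modal node degree 3", {
  spec <- scene_spec(shape = c(1, 1, 90, 96), spacing = c(0.15, 0.15),
    objects = list(lattice_object(c(0, 6.6, 7.0), hex_radius_um = 1.5,
                                  tube_radius_um = 0.22, n_rings = 2,
                                  intensity = 150)),
    psf_sigma_um = 0.1, noise = list(poisson = TRUE, gaussian_sd = 2),
    background = 10, seed = 3)
  res <- run_scene(spec)
  h <- res$hierarchies[[1]]
  big <- which.max(tabulate(h$organelle_labels[h$organelle_labels > 0]))
  sg <- build_skeleton_graph(h, organelle_id = big)
  tm <- topology_metrics(sg)
  deg <- tm$per_node$degree[tm$per_node$kind == "junction"]
  tab <- table(deg)
  expect_equal(as.integer(names(tab)[which.max(tab)]), 3L)
})

test_that("multi-mesh levels follow the power-of-two rule", {
  # straight path of 9 nodes: levels jump 1,2,4,8 with 8,4,2,1 edges
  m <- array(FALSE, c(1, 5, 13)); m[1, 3, 3:11] <- TRUE
  h <- hierarchy_from_mask(m)
  expect_equal(nrow(h$nodes), 9L)
  mm <- build_multimesh(h, organelle_id = 1)
  expect_equal(length(mm$levels), 4L)
  expect_equal(vapply(mm$levels, nrow, 1L), c(8L, 4L, 2L, 1L))
  for (l in seq_along(mm$levels)) {
    lv <- mm$levels[[l]]
    expect_true(all((lv[, "j"] - lv[, "i"]) == 2^(l - 1)))
    expect_true(all(lv[, "i"] %% 2^(l - 1) == 0))
  }
  # level 0 contains every consecutive pair of the traversal
  expect_equal(mm$levels[[1]][, "i"], 0:7)
  # 2^k + 1 nodes in general
  for (k in 2:4) {
    mk <- array(FALSE, c(1, 3, 2^k + 3)); mk[1, 2, 2:(2^k + 2)] <- TRUE
    hk <- hierarchy_from_mask(mk)
    mmk <- build_multimesh(hk, organelle_id = 1)
    expect_equal(vapply(mmk$levels, nrow, 1L), as.integer(2^(k:0)))
  }
})

test_that("single-node organelles yield edgeless meshes; meshes are deterministic", {
  sv <- array(FALSE, c(1, 7, 7)); sv[1, 3:4, 3:4] <- TRUE
  h <- hierarchy_from_mask(sv)
  h$nodes <- h$nodes[1, , drop = FALSE]      # restrict to a single node
  mm <- build_multimesh(h, organelle_id = 1)
  expect_equal(length(mm$levels), 0L)
  expect_equal(nrow(mm$edge_list), 0L)

  hy <- hierarchy_from_mask(shape_y())
  m1 <- build_multimesh(hy, organelle_id = 1)
  m2 <- build_multimesh(hy, organelle_id = 1)
  expect_identical(m1$order, m2$order)
  expect_identical(m1$adjacency, m2$adjacency)
  # every skeleton-adjacency consecutive pair is present at level 0
  expect_equal(nrow(m1$levels[[1]]), length(m1$order) - 1L)
})
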
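# Convex hull helpers for solidity: 2D via grDevices::chull, 3D via an
# incremental quickhull. Solidity compares voxel counts, so the hull is
# rasterized back onto the voxel grid (voxel centres inside the hull), the
# convention regionprops-style measurements use.

# incremental 3D convex hull; pts: n x 3 (distinct rows recommended)
# returns matrix of faces (rows of 3 point indices, outward-oriented), or
# NULL when the point set is degenerate (rank < 3)
quickhull3 <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n < 4) return(NULL)
  scale <- max(abs(pts)) + 1
  tol <- tol * scale
  # initial extreme points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  if (i1 == i2) return(NULL)
  d12 <- pts[i2, ] - pts[i1, ]
  # farthest from the line i1-i2
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  rel <- sweep(pts, 2, pts[i1, ])
  crn <- t(apply(rel, 1, function(v) cr(d12, v)))
  dline <- sqrt(rowSums(crn^2))
  i3 <- which.max(dline)
  if (dline[i3] <= tol) return(NULL)
  nrm <- cr(d12, pts[i3, ] - pts[i1, ])
  dplane <- as.vector(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(abs(dplane))
  if (abs(dplane[i4]) <= tol) return(NULL)

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    nn <- cr(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nn * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- list(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))
  face_normal <- function(f) {
    nn <- cr(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nn / sqrt(sum(nn^2))
  }
  above <- function(f, idx) {
    nn <- face_normal(f)
    as.vector(sweep(pts[idx, , drop = FALSE], 2, pts[f[1], ]) %*% nn)
  }
  outside <- vector("list", 4)
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (k in 1:4) {
    if (!length(rest)) { outside[[k]] <- integer(); next }
    dv <- above(faces[[k]], rest)
    outside[[k]] <- rest[dv > tol]
  }
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  repeat {
    fi <- which(vapply(outside, length, 1L) > 0)
    if (!length(fi)) break
    fi <- fi[1]
    cand <- outside[[fi]]
    dv <- above(faces[[fi]], cand)
    p <- cand[which.max(dv)]
    # visible faces
    vis <- vapply(seq_along(faces), function(k) above(faces[[k]], p) > tol, TRUE)
    vis_idx <- which(vis)
    # horizon edges: edges of visible faces shared with a non-visible face
    ecount <- new.env()
    for (k in vis_idx) {
      f <- faces[[k]]
      for (e in list(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))) {
        key <- edge_key(e[1], e[2])
        prev <- if (!is.null(ecount[[key]])) ecount[[key]] else list(cnt = 0, e = e)
        prev$cnt <- prev$cnt + 1
        ecount[[key]] <- prev
      }
    }
    horizon <- Filter(function(v) v$cnt == 1, as.list(ecount))
    pool <- unique(unlist(outside[vis_idx]))
    pool <- setdiff(pool, p)
    faces <- faces[!vis]
    outside <- outside[!vis]
    for (h in horizon) {
      f <- orient(c(h$e[1], h$e[2], p))
      faces[[length(faces) + 1]] <- f
      if (length(pool)) {
        dv <- above(f, pool)
        outside[[length(outside) + 1]] <- pool[dv > tol]
      } else outside[[length(outside) + 1]] <- integer()
    }
  }
  do.call(rbind, faces)
}

# count voxel centres (0-based integer grid coords within bbox) inside the
# hull of the given 0-based voxel coordinates; works in 1D/2D/3D after
# dropping axes without extent
hull_voxel_count <- function(coords) {
  coords <- rbind(coords)
  rng <- apply(coords, 2, range)
  live <- which(rng[2, ] > rng[1, ])
  if (length(live) == 0) return(1)
  if (length(live) == 1) return(rng[2, live] - rng[1, live] + 1)
  cc <- coords[, live, drop = FALSE]
  grid <- as.matrix(expand.grid(lapply(live, function(a) rng[1, a]:rng[2, a])))
  if (length(live) == 2) {
    h <- grDevices::chull(cc[, 1], cc[, 2])
    poly <- cc[h, , drop = FALSE]
    k <- nrow(poly)
    # ensure counter-clockwise orientation for the half-plane test
    sa <- sum(poly[, 1] * poly[c(2:k, 1), 2] - poly[c(2:k, 1), 1] * poly[, 2])
    if (sa < 0) poly <- poly[k:1, , drop = FALSE]
    inside <- rep(TRUE, nrow(grid))
    for (i in seq_len(k)) {
      j <- if (i == k) 1 else i + 1
      e <- poly[j, ] - poly[i, ]
      rel <- sweep(grid, 2, poly[i, ])
      crossz <- e[1] * rel[, 2] - e[2] * rel[, 1]
      inside <- inside & crossz >= -1e-9
    }
    return(sum(inside))
  }
  faces <- quickhull3(cc)
  if (is.null(faces)) {
    # degenerate (non-axis-aligned plane or line): fall back to the point count
    return(nrow(unique(coords)))
  }
  inside <- rep(TRUE, nrow(grid))
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    a <- cc[f[1], ]; b <- cc[f[2], ]; d <- cc[f[3], ]
    nn <- c((b[2] - a[2]) * (d[3] - a[3]) - (b[3] - a[3]) * (d[2] - a[2]),
            (b[3] - a[3]) * (d[1] - a[1]) - (b[1] - a[1]) * (d[3] - a[3]),
            (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1]))
    inside <- inside & (sweep(grid, 2, a) %*% nn) <= 1e-9 * (sum(abs(nn)) + 1)
  }
  sum(inside)
}
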
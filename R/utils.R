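# Shared low-level helpers.
#
# Conventions used throughout the package:
#  * per-frame arrays are 3D (z, y, x); 2D data carry a singleton z axis
#  * voxel coordinates exchanged between functions are 0-based (z, y, x)
#  * physical coordinate = 0-based index * spacing (microns)

#' @useDynLib organellometry, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# linear 1-based array indices -> 0-based (z, y, x) coordinate matrix
coords_from_index <- function(idx, dim3) {
  nz <- dim3[1]; ny <- dim3[2]
  i0 <- idx - 1L
  z <- i0 %% nz
  r <- i0 %/% nz
  y <- r %% ny
  x <- r %/% ny
  cbind(z = z, y = y, x = x)
}

# 0-based (z, y, x) coordinates -> linear 1-based array indices
index_from_coords <- function(coords, dim3) {
  coords <- rbind(coords)
  as.integer(coords[, 1] + dim3[1] * (coords[, 2] + dim3[2] * coords[, 3]) + 1)
}

# physical (micron) coordinates of 0-based voxel coordinates
phys_coords <- function(coords, spacing3) {
  sweep(rbind(coords), 2, spacing3, `*`)
}

row_norms <- function(m) sqrt(rowSums(rbind(m)^2))

# frame t of a canonical (T, Z, Y, X) array as a 3D (z, y, x) array
frame_array <- function(data, t) {
  d <- dim(data)
  array(data[t, , , ], dim = d[2:4])
}

is_flat <- function(dim3) dim3[1] == 1L

# spacing as length-3 (dz, dy, dx); 2D stacks get a unit placeholder dz
# (the singleton z axis never contributes distances)
spacing3_of <- function(spacing) {
  if (length(spacing) == 2) c(1, spacing) else as.numeric(spacing)
}
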
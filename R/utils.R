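# Internal grid helpers shared by the phantom, montage and solver code.
# Convention: world origin at the sphere centre, +z vertex, +y nasion,
# +x right preauricular; voxel centre of index (i,j,k) (1-based) sits at
# origin + (i-1, j-1, k-1) * voxel_size, all in mm.

#' @keywords internal
voxel_axes <- function(dim, voxel_size, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dim[a]) - 1) * voxel_size)
}

# Squared radius (mm^2) of every voxel centre, as a 3-D array.
#' @keywords internal
radius2_array <- function(dim, voxel_size, origin) {
  ax <- voxel_axes(dim, voxel_size, origin)
  x2 <- ax[[1]]^2
  y2 <- ax[[2]]^2
  z2 <- ax[[3]]^2
  r2 <- array(0, dim)
  r2 <- r2 + rep(x2, times = dim[2] * dim[3])
  r2 <- r2 + rep(rep(y2, each = dim[1]), times = dim[3])
  r2 <- r2 + rep(z2, each = dim[1] * dim[2])
  r2
}

# Per-axis coordinate arrays (mm), same shape as the volume.
#' @keywords internal
coord_arrays <- function(dim, voxel_size, origin) {
  ax <- voxel_axes(dim, voxel_size, origin)
  list(
    x = array(rep(ax[[1]], times = dim[2] * dim[3]), dim),
    y = array(rep(rep(ax[[2]], each = dim[1]), times = dim[3]), dim),
    z = array(rep(ax[[3]], each = dim[1] * dim[2]), dim)
  )
}

#' @keywords internal
normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length direction", call. = FALSE)
  v / n
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle (degrees) between two unit vectors, safe against round-off.
#' @keywords internal
angle_deg <- function(a, b) {
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

# World -> (fractional, 1-based) voxel index.
#' @keywords internal
world_to_index <- function(points, voxel_size, origin) {
  sweep(points, 2, origin) / voxel_size + 1
}

# Nearest-voxel linear indices for an n x 3 matrix of world points;
# NA for points outside the grid.
#' @keywords internal
nearest_linear_index <- function(points, dim, voxel_size, origin) {
  idx <- round(world_to_index(points, voxel_size, origin))
  ok <- idx[, 1] >= 1 & idx[, 1] <= dim[1] &
    idx[, 2] >= 1 & idx[, 2] <= dim[2] &
    idx[, 3] >= 1 & idx[, 3] <= dim[3]
  lin <- rep(NA_integer_, nrow(idx))
  lin[ok] <- as.integer(idx[ok, 1] + (idx[ok, 2] - 1) * dim[1] +
    (idx[ok, 3] - 1) * dim[1] * dim[2])
  lin
}

# Trilinear interpolation of a 3-D array at world points (n x 3).
# Points outside the grid, or with any NA corner, return NA.
#' @keywords internal
trilinear <- function(arr, points, voxel_size, origin) {
  dim <- dim(arr)
  f <- world_to_index(points, voxel_size, origin)
  i0 <- floor(f)
  t <- f - i0
  out <- rep(NA_real_, nrow(points))
  ok <- i0[, 1] >= 1 & i0[, 1] < dim[1] &
    i0[, 2] >= 1 & i0[, 2] < dim[2] &
    i0[, 3] >= 1 & i0[, 3] < dim[3]
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  t <- t[ok, , drop = FALSE]
  n12 <- dim[1] * dim[2]
  base <- i0[, 1] + (i0[, 2] - 1) * dim[1] + (i0[, 3] - 1) * n12
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * t[, 1] + (1 - dx) * (1 - t[, 1])) *
      (dy * t[, 2] + (1 - dy) * (1 - t[, 2])) *
      (dz * t[, 3] + (1 - dz) * (1 - t[, 3]))
    acc <- acc + w * arr[base + dx + dy * dim[1] + dz * n12]
  }
  out[ok] <- acc
  out
}

# Deterministic quasi-uniform directions on the unit sphere
# (Fibonacci lattice).
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Single 6-connected component check / flood fill over a logical array.
# Returns the logical array of voxels reachable from `seed` (logical array)
# through `domain` (logical array).
#' @keywords internal
flood_fill6 <- function(domain, seed) {
  dim <- dim(domain)
  reach <- seed & domain
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-dim[1], , ]
    grown[-dim[1], , ] <- grown[-dim[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -dim[2], ]
    grown[, -dim[2], ] <- grown[, -dim[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -dim[3]]
    grown[, , -dim[3]] <- grown[, , -dim[3]] | reach[, , -1]
    grown <- grown & domain
    if (!any(grown & !reach)) break
    reach <- grown
  }
  reach
}
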
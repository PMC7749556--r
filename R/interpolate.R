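# Trilinear interpolation of tensor and scalar volumes in world coordinates.
#
# Convention (pinned for reproducible tracking): voxel indices are 0-based,
# the affine maps voxel *centers* to world mm, and the interpolation hull is
# the box of voxel centers -- fractional voxel coordinates in [0, n-1] per
# axis. Points outside that hull (including the outer half-voxel shell) are
# an out-of-bounds event.

world_to_voxel <- function(points, affine) {
  points <- matrix(points, ncol = 3)
  inv <- solve(affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

# Weights and flat (column-major) indices of the 8 voxel centers around a
# single fractional voxel coordinate. Returns NULL when out of bounds.
trilinear_stencil <- function(frac, dm) {
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > dm - 1L)) return(NULL)
  i0 <- pmin(floor(frac), dm - 2L)   # keep the upper face usable
  i0 <- pmax(i0, 0)
  t <- frac - i0
  wx <- c(1 - t[1], t[1]); wy <- c(1 - t[2], t[2]); wz <- c(1 - t[3], t[3])
  w <- as.vector(outer(outer(wx, wy), wz))       # 8 weights, x fastest
  ix <- i0[1] + c(0L, 1L); iy <- i0[2] + c(0L, 1L); iz <- i0[3] + c(0L, 1L)
  flat <- as.vector(outer(outer(ix + 1L, iy * dm[1], "+"),
                          iz * dm[1] * dm[2], "+"))
  list(w = w, idx = flat)
}

# Fast internal sampler used by the tracker: `values` is an nvox x k matrix
# of flattened components. Returns numeric k-vector or NULL when OOB.
interp_at <- function(values, dm, frac) {
  st <- trilinear_stencil(frac, dm)
  if (is.null(st)) return(NULL)
  as.vector(crossprod(values[st$idx, , drop = FALSE], st$w))
}

#' Interpolate a tensor field at a world point
#'
#' Component-wise trilinear interpolation over the centers of the eight
#' voxels surrounding the point; at a voxel center this returns that
#' voxel's tensor exactly. Interpolating component-wise preserves symmetry
#' (and positive semi-definiteness, as a convex combination of PSD
#' matrices).
#'
#' @param field a [tensor_field()].
#' @param point world coordinates, mm (length 3).
#' @return A symmetric 3 x 3 tensor matrix.
#' @export
interpolate_tensor <- function(field, point) {
  dm <- dim(field$D)[1:3]
  frac <- as.vector(world_to_voxel(point, field$affine))
  vals <- interp_at(matrix(field$D, prod(dm), 6), dm, frac)
  if (is.null(vals)) {
    stop_tendtract("out_of_bounds",
                   "point (%.3f, %.3f, %.3f) mm lies outside the interpolation hull",
                   point[1], point[2], point[3])
  }
  tensor6_to_mat(vals)
}

#' Interpolate a scalar map at a world point
#'
#' @param map a [scalar_map()].
#' @param point world coordinates, mm (length 3).
#' @return Interpolated scalar value.
#' @export
interpolate_scalar <- function(map, point) {
  dm <- dim(map$values)
  frac <- as.vector(world_to_voxel(point, map$affine))
  val <- interp_at(matrix(as.vector(map$values), prod(dm), 1), dm, frac)
  if (is.null(val)) {
    stop_tendtract("out_of_bounds",
                   "point (%.3f, %.3f, %.3f) mm lies outside the interpolation hull",
                   point[1], point[2], point[3])
  }
  val
}
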
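# Cubic B-spline free-form deformation: tensor-product evaluation of a
# control-point displacement grid on the voxel grid, and the transposed
# operation that projects a per-voxel force field onto the control points.
# Everything is separable, so both directions reduce to three small matrix
# products.

# Cubic B-spline basis values for local coordinate t in [0, 1).
bspline_weights <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# Per-axis basis matrix (n voxels x ncp control points).
# Control point i sits at cp_origin + (i - 1) * delta (mm).
bspline_axis_matrix <- function(coords_mm, delta, cp_origin, ncp) {
  u <- (coords_mm - cp_origin) / delta
  cell <- pmin(pmax(floor(u), 1), ncp - 3)  # cells use cp cell..cell+3
  t <- u - cell
  Wm <- bspline_weights(t)
  B <- matrix(0, length(coords_mm), ncp)
  for (l in 0:3)
    B[cbind(seq_along(coords_mm), cell + l)] <- Wm[, l + 1]
  B
}

# Control grid covering a volume (dims, spacing, origin) at cp spacing
# delta (mm), with one support point before and two past each end.
bspline_grid <- function(dim, spacing, origin, delta) {
  ext <- (dim - 1) * spacing
  ncp <- pmax(4L, as.integer(ceiling(ext / delta)) + 3L)
  cp_origin <- origin - delta
  B <- lapply(1:3, function(a) {
    coords <- origin[a] + (seq_len(dim[a]) - 1) * spacing[a]
    bspline_axis_matrix(coords, delta, cp_origin[a], ncp[a])
  })
  list(ncp = ncp, delta = delta, cp_origin = cp_origin, B = B)
}

# Evaluate one displacement component: coefficient array -> voxel array.
bspline_eval_component <- function(grid, C) {
  a <- tensor_apply(grid$B[[1]], C, 1L)
  a <- tensor_apply(grid$B[[2]], a, 2L)
  tensor_apply(grid$B[[3]], a, 3L)
}

# Transpose: per-voxel force array -> gradient wrt coefficients.
bspline_project_component <- function(grid, Fc) {
  a <- tensor_apply(t(grid$B[[1]]), Fc, 1L)
  a <- tensor_apply(t(grid$B[[2]]), a, 2L)
  tensor_apply(t(grid$B[[3]]), a, 3L)
}

# Evaluate the full transform's displacement (mm) on an arbitrary voxel
# grid (dims/spacing/origin), e.g. the full-resolution grid after
# registering on a shrunk one.
bspline_displacement <- function(transform, dim, spacing, origin) {
  g <- transform$grid
  B <- lapply(1:3, function(a) {
    coords <- origin[a] + (seq_len(dim[a]) - 1) * spacing[a]
    bspline_axis_matrix(coords, g$delta, g$cp_origin[a], g$ncp[a])
  })
  gg <- list(ncp = g$ncp, delta = g$delta, cp_origin = g$cp_origin, B = B)
  vec <- array(0, c(dim, 3L))
  for (c3 in 1:3)
    vec[, , , c3] <- bspline_eval_component(gg, transform$coef[, , , c3])
  vec
}
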
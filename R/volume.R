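# S3 containers for volumes on a physical grid.
#
# Conventions used throughout the package:
#   * axis 1 (x): patient right -> left
#   * axis 2 (y): posterior -> anterior
#   * axis 3 (z): inferior -> superior
#   * voxel indices are 1-based in R; physical position of voxel (i,j,k) is
#     origin + (c(i,j,k) - 1) * spacing, in mm.
#   * displacement fields are stored in physical mm, in the pull-back
#     (resampling) convention: warping samples the source volume at
#     x + d(x) (see [warp_volume()]).

#' Construct an organ label volume
#'
#' The shared ground-truth anatomy of a phantom instance: a 3D integer label
#' map with physical spacing plus a catalog mapping label ids to organ names.
#' Label 0 is background (air) and is always present in the catalog.
#'
#' @param labels 3D integer array, one organ id per voxel.
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @param organ_catalog named integer vector or list mapping organ name to id;
#'   must cover every nonzero label present in `labels`.
#' @return An object of class `organ_label_volume`.
#' @export
organ_label_volume <- function(labels, spacing, origin = c(0, 0, 0),
                               organ_catalog) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  catalog <- unlist(organ_catalog)
  if (is.null(names(catalog)) || any(names(catalog) == ""))
    stop("`organ_catalog` must be named (organ name -> id)")
  storage.mode(labels) <- "integer"
  if (!0L %in% catalog)
    catalog <- c(background = 0L, catalog)
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(present, as.integer(catalog))
  if (length(missing) > 0)
    stop("labels not in organ_catalog: ", paste(missing, collapse = ", "))
  structure(list(labels = labels,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 organ_catalog = as.integer(catalog) |>
                   stats::setNames(names(catalog))),
            class = "organ_label_volume")
}

#' @export
print.organ_label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("organ_label_volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "/")))
  cat("organs:", paste(sprintf("%s=%d", names(x$organ_catalog),
                               x$organ_catalog), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a modality volume
#'
#' A scalar 3D image tagged with its modality, windowing interval and
#' normalization state. When `normalized` is `TRUE` all intensities must lie
#' in \[-1, 1\].
#'
#' @param intensities 3D numeric array.
#' @param modality one of `"CT"`, `"CBCT"`, `"MRI"`.
#' @param spacing voxel spacing in mm.
#' @param origin physical origin in mm.
#' @param window optional numeric length-2 `(low, high)` in native units.
#' @param normalized logical; `TRUE` once mapped to \[-1, 1\].
#' @return An object of class `modality_volume`.
#' @export
modality_volume <- function(intensities, modality = c("CT", "CBCT", "MRI"),
                            spacing, origin = c(0, 0, 0), window = NULL,
                            normalized = FALSE) {
  modality <- match.arg(modality)
  if (length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] >= window[2])
      stop("`window` must be (low, high) with low < high")
  }
  if (normalized) {
    rng <- range(intensities)
    if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
      stop("normalized volume must lie in [-1, 1]")
  }
  structure(list(intensities = intensities, modality = modality,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 window = window, normalized = isTRUE(normalized)),
            class = "modality_volume")
}

#' @export
print.modality_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("modality_volume [%s]: %d x %d x %d, spacing %s mm, %s\n",
              x$modality, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "/"),
              if (x$normalized) "normalized [-1,1]" else "native units"))
  invisible(x)
}

#' Construct a displacement field
#'
#' Per-voxel 3-vectors in physical mm linking two motion states, stored in
#' the pull-back convention used by [warp_volume()]: a volume in state
#' `to_state` is produced by sampling the `from_state` volume at `x + d(x)`.
#'
#' @param vectors 4D numeric array `(nx, ny, nz, 3)`, mm.
#' @param spacing,origin grid geometry matching the associated phantom.
#' @param from_state,to_state motion-state tags (e.g. "exhaled", "inhaled").
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing, origin = c(0, 0, 0),
                               from_state = "exhaled", to_state = "inhaled") {
  dm <- dim(vectors)
  if (length(dm) != 4L || dm[4] != 3L)
    stop("`vectors` must be a (nx, ny, nz, 3) array")
  if (identical(from_state, to_state) && any(vectors != 0))
    stop("a field between identical motion states must be zero")
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 from_state = from_state, to_state = to_state),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors)
  mags <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 +
                 x$vectors[, , , 3]^2)
  cat(sprintf(
    "displacement_field %s -> %s: %d x %d x %d, max |d| = %.2f mm\n",
    x$from_state, x$to_state, d[1], d[2], d[3], max(mags)))
  invisible(x)
}

# ---- interpolation -------------------------------------------------------

# Sample a 3D array at fractional voxel coordinates (1-based), n x 3 matrix.
# Coordinates are clamped to the valid range (edge extension).
sample_volume <- function(arr, pts, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(arr)
  cx <- pmin(pmax(pts[, 1], 1), d[1])
  cy <- pmin(pmax(pts[, 2], 1), d[2])
  cz <- pmin(pmax(pts[, 3], 1), d[3])
  if (interpolation == "nearest") {
    return(arr[cbind(round(cx), round(cy), round(cz))])
  }
  x0 <- pmin(floor(cx), d[1] - 1L); y0 <- pmin(floor(cy), d[2] - 1L)
  z0 <- pmin(floor(cz), d[3] - 1L)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  idx <- function(i, j, k) arr[cbind(i, j, k)]
  v000 <- idx(x0,     y0,     z0)
  v100 <- idx(x0 + 1, y0,     z0)
  v010 <- idx(x0,     y0 + 1, z0)
  v110 <- idx(x0 + 1, y0 + 1, z0)
  v001 <- idx(x0,     y0,     z0 + 1)
  v101 <- idx(x0 + 1, y0,     z0 + 1)
  v011 <- idx(x0,     y0 + 1, z0 + 1)
  v111 <- idx(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# Identity voxel-coordinate grid as an n x 3 matrix for dims d.
coord_grid <- function(d) {
  cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

#' Warp a volume through a displacement field
#'
#' Resamples `volume` through `field` using the pull-back convention:
#' `out(x) = volume(x + d(x))` with `d` in mm converted to voxel units via
#' the field's spacing. Label volumes are always resampled with
#' nearest-neighbour interpolation.
#'
#' @param volume an [organ_label_volume()], [modality_volume()], or bare 3D
#'   array (then `field`'s spacing applies).
#' @param field a [displacement_field()] whose grid matches `volume`.
#' @param interpolation `"linear"` or `"nearest"`; ignored (forced to
#'   nearest) for label volumes.
#' @return A warped object of the same class as `volume`.
#' @export
warp_volume <- function(volume, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  arr <- volume_array(volume)
  d <- dim(arr)
  if (!identical(d, dim(field$vectors)[1:3]))
    stop("field shape does not match volume shape")
  if (inherits(volume, "organ_label_volume")) interpolation <- "nearest"
  pts <- coord_grid(d)
  dv <- matrix(field$vectors, ncol = 3L)
  pts <- pts + sweep(dv, 2L, field$spacing, "/")
  out <- array(sample_volume(arr, pts, interpolation), dim = d)
  set_volume_array(volume, out)
}

volume_array <- function(volume) {
  if (inherits(volume, "organ_label_volume")) volume$labels
  else if (inherits(volume, "modality_volume")) volume$intensities
  else if (is.array(volume) && length(dim(volume)) == 3L) volume
  else stop("unsupported volume type")
}

set_volume_array <- function(volume, arr) {
  if (inherits(volume, "organ_label_volume")) {
    storage.mode(arr) <- "integer"
    volume$labels <- arr
  } else if (inherits(volume, "modality_volume")) {
    volume$intensities <- arr
  } else {
    volume <- arr
  }
  volume
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the inverse resampling field:
#' `d_inv(x) = -d(x + d_inv(x))`. Converges for smooth fields whose Jacobian
#' stays away from singularity (true of the respiratory model here).
#'
#' @param field a [displacement_field()].
#' @param iterations maximum fixed-point iterations.
#' @param tol convergence tolerance on the max update, mm.
#' @return The inverse [displacement_field()] (states swapped).
#' @export
invert_displacement_field <- function(field, iterations = 30, tol = 0.01) {
  d <- dim(field$vectors)[1:3]
  pts0 <- coord_grid(d)
  dv <- matrix(0, nrow = prod(d), ncol = 3L)
  fwd <- lapply(1:3, function(c3) field$vectors[, , , c3])
  for (it in seq_len(iterations)) {
    pts <- pts0 + sweep(dv, 2L, field$spacing, "/")
    new <- -vapply(1:3, function(c3) sample_volume(fwd[[c3]], pts, "linear"),
                   numeric(prod(d)))
    delta <- max(abs(new - dv))
    dv <- new
    if (delta < tol) break
  }
  displacement_field(array(dv, dim = c(d, 3L)), spacing = field$spacing,
                     origin = field$origin, from_state = field$to_state,
                     to_state = field$from_state)
}

# ---- separable Gaussian smoothing ---------------------------------------

# 1D Gaussian band matrix with reflected boundaries (n x n).
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  m <- matrix(0, n, n)
  idx <- seq_len(n)
  for (t in -r:r) {
    src <- idx + t
    src <- ifelse(src < 1, 2 - src, src)
    src <- ifelse(src > n, 2 * n - src, src)
    m[cbind(idx, src)] <- m[cbind(idx, src)] + k[t + r + 1]
  }
  m
}

# Apply matrix m along one axis of a 3D array.
tensor_apply <- function(m, arr, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- if (axis == 1L) arr else aperm(arr, perm)
  da <- dim(a)
  out <- m %*% matrix(a, nrow = da[1])
  out <- array(out, dim = c(nrow(m), da[2], da[3]))
  if (axis == 1L) out
  else aperm(out, order(perm))
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
smooth_gaussian <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma[ax] > 0)
      arr <- tensor_apply(gauss_band(d[ax], sigma[ax]), arr, ax)
  }
  arr
}

# ---- IO ------------------------------------------------------------------

#' Write and read volumes as NIfTI
#'
#' Scalar volumes are written as 3D NIfTI, displacement fields as 4D
#' `(nx, ny, nz, 3)` NIfTI; the organ catalog of a label volume goes to a
#' JSON sidecar `<path>.labels.json`.
#'
#' @param volume an [organ_label_volume()], [modality_volume()] or
#'   [displacement_field()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "displacement_field")) {
    img <- RNifti::asNifti(volume$vectors)
    RNifti::pixdim(img) <- c(volume$spacing, 1)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  arr <- volume_array(volume)
  img <- RNifti::asNifti(arr + 0)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  if (inherits(volume, "organ_label_volume")) {
    jsonlite::write_json(as.list(volume$organ_catalog),
                         paste0(path, ".labels.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param what one of `"label"`, `"modality"`, `"field"`.
#' @param ... passed to the respective constructor (e.g. `modality`).
#' @export
read_volume <- function(path, what = c("modality", "label", "field"), ...) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  arr <- as.array(img)
  if (what == "field") {
    return(displacement_field(arr, spacing = sp, ...))
  }
  if (what == "label") {
    sidecar <- paste0(path, ".labels.json")
    catalog <- if (file.exists(sidecar))
      unlist(jsonlite::read_json(sidecar))
    else stats::setNames(sort(unique(as.vector(arr))),
                         paste0("organ_", sort(unique(as.vector(arr)))))
    return(organ_label_volume(arr, spacing = sp, organ_catalog = catalog, ...))
  }
  modality_volume(arr, spacing = sp, ...)
}
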
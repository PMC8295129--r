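# Procedural abdominal phantom: parameterized superellipsoids and tubes
# composited back-to-front with fixed precedence (vessels over liver over
# body), standing in for a licensed anthropomorphic phantom as the shared
# source of anatomy, organ masks and motion ground truth.

#' Phantom generation parameters
#'
#' @param dim grid size in voxels (x, y, z).
#' @param spacing voxel spacing in mm.
#' @param body_scale global scale factor applied to all organ sizes.
#' @param arms include arm labels (MRI-style anatomy) or not (CT/CBCT style).
#' @param organ_jitter fraction by which per-organ semi-axes are jittered
#'   uniformly, emulating inter-subject variability.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(96, 96, 96), spacing = c(2.5, 2.5, 2.5),
                           body_scale = 1, arms = FALSE, organ_jitter = 0.05) {
  stopifnot(length(dim) == 3, all(dim >= 8), length(spacing) == 3,
            all(spacing > 0), body_scale > 0,
            organ_jitter >= 0, organ_jitter < 1)
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 body_scale = body_scale, arms = isTRUE(arms),
                 organ_jitter = organ_jitter),
            class = "phantom_config")
}

#' Organ label ids used by generated phantoms
#'
#' @return Named integer vector mapping organ name to label id.
#' @export
organ_ids <- function() {
  c(background = 0L, body = 1L, lung_left = 2L, lung_right = 3L,
    liver = 4L, hepatic_vessel = 5L, kidney_left = 6L, kidney_right = 7L,
    spleen = 8L, stomach = 9L, spine = 10L, aorta = 11L,
    arm_left = 12L, arm_right = 13L)
}

# Paint a superellipsoid |dx/a|^e + |dy/b|^e + |dz/c|^e <= 1 into `labels`.
# center and semi-axes in mm (physical); exponent e controls squareness.
paint_superellipsoid <- function(labels, grid, center, semi, exponent, id) {
  inside <- (abs(grid$x - center[1]) / semi[1])^exponent +
    (abs(grid$y - center[2]) / semi[2])^exponent +
    (abs(grid$z - center[3]) / semi[3])^exponent <= 1
  labels[inside] <- id
  labels
}

# Vertical tube: superellipse cross-section in (x, y), z-range in mm.
paint_tube <- function(labels, grid, center_xy, semi_xy, exponent, zrange, id,
                       tilt = c(0, 0)) {
  cx <- center_xy[1] + tilt[1] * grid$z
  cy <- center_xy[2] + tilt[2] * grid$z
  inside <- (abs(grid$x - cx) / semi_xy[1])^exponent +
    (abs(grid$y - cy) / semi_xy[2])^exponent <= 1 &
    grid$z >= zrange[1] & grid$z <= zrange[2]
  labels[inside] <- id
  labels
}

#' Generate a labeled abdominal phantom
#'
#' Produces the exhaled-state ground-truth anatomy: body outline, two lungs,
#' liver with internal hepatic vessels, two kidneys, spleen, stomach, spine,
#' aorta, and (optionally) arms. Organ sizes are jittered per organ by
#' `organ_jitter` so different seeds give different "subjects". The whole
#' liver is always inside the grid. Generation is deterministic given
#' `(config, seed)`.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed controlling organ-size jitter.
#' @return An [organ_label_volume()] in the exhaled reference state.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$dim
  sp <- config$spacing
  ext <- (d - 1) * sp            # physical extent per axis, mm
  labels <- array(0L, dim = d)

  # physical coordinate arrays (recycled to full grid)
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  grid <- list(
    x = array(rep(x, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(y, each = d[1]), times = d[3]), dim = d),
    z = array(rep(z, each = d[1] * d[2]), dim = d))

  cx <- ext[1] / 2; cy <- ext[2] / 2
  s <- config$body_scale
  set.seed(as.integer(seed))
  jit <- function() {
    j <- config$organ_jitter
    if (j == 0) 1 else stats::runif(1, 1 - j, 1 + j)
  }

  # Organ layout in fractions of the body extent. z fractions: diaphragm
  # dome sits near 0.62 of the axial extent; lungs above, abdomen below.
  body_a <- 0.42 * ext[1] * s; body_b <- 0.30 * ext[2] * s
  labels <- paint_tube(labels, grid, c(cx, cy), c(body_a, body_b), 2.5,
                       c(0, ext[3]), organ_ids()[["body"]])

  if (config$arms) {
    arm_r <- 0.045 * ext[1] * s
    for (side in c(-1, 1)) {
      id <- if (side < 0) organ_ids()[["arm_left"]] else
        organ_ids()[["arm_right"]]
      # patient left = +x; arm_left on +x side
      ax <- cx - side * (body_a + arm_r * 1.6)
      labels <- paint_tube(labels, grid, c(ax, cy), c(arm_r, arm_r), 2,
                           c(0, ext[3]), id)
    }
  }

  # lungs: upper thorax, left/right ellipsoids (patient right = -x side)
  lung_z <- 0.80 * ext[3]
  lung_semi <- c(0.16 * ext[1] * jit(), 0.20 * ext[2] * jit(),
                 0.22 * ext[3] * jit()) * s
  labels <- paint_superellipsoid(labels, grid,
                                 c(cx - 0.20 * ext[1] * s, cy, lung_z),
                                 lung_semi, 2, organ_ids()[["lung_right"]])
  labels <- paint_superellipsoid(labels, grid,
                                 c(cx + 0.20 * ext[1] * s, cy, lung_z),
                                 lung_semi * c(1, 1, 0.95), 2,
                                 organ_ids()[["lung_left"]])

  # stomach: left anterior, below diaphragm
  labels <- paint_superellipsoid(
    labels, grid,
    c(cx + 0.17 * ext[1] * s, cy + 0.10 * ext[2] * s, 0.52 * ext[3]),
    c(0.11, 0.10, 0.11) * ext * jit() * s, 2, organ_ids()[["stomach"]])

  # spleen: left posterior
  labels <- paint_superellipsoid(
    labels, grid,
    c(cx + 0.26 * ext[1] * s, cy - 0.12 * ext[2] * s, 0.50 * ext[3]),
    c(0.075, 0.09, 0.10) * ext * jit() * s, 2, organ_ids()[["spleen"]])

  # kidneys: posterior, lower abdomen
  kid_semi <- c(0.065, 0.075, 0.105) * ext * jit() * s
  labels <- paint_superellipsoid(
    labels, grid, c(cx - 0.16 * ext[1] * s, cy - 0.14 * ext[2] * s,
                    0.30 * ext[3]),
    kid_semi, 2, organ_ids()[["kidney_right"]])
  labels <- paint_superellipsoid(
    labels, grid, c(cx + 0.16 * ext[1] * s, cy - 0.14 * ext[2] * s,
                    0.28 * ext[3]),
    kid_semi, 2, organ_ids()[["kidney_left"]])

  # liver: large right-side organ under the right lung; whole liver in grid
  liver_semi <- c(0.225 * ext[1] * jit(), 0.21 * ext[2] * jit(),
                  0.185 * ext[3] * jit()) * s
  liver_center <- c(cx - 0.15 * ext[1] * s, cy + 0.02 * ext[2] * s,
                    0.48 * ext[3])
  labels <- paint_superellipsoid(labels, grid, liver_center, liver_semi, 2.3,
                                 organ_ids()[["liver"]])

  # spine: posterior midline column
  labels <- paint_tube(labels, grid,
                       c(cx, cy - 0.21 * ext[2] * s),
                       c(0.055, 0.05) * ext[1:2] * s, 2, c(0, ext[3]),
                       organ_ids()[["spine"]])

  # aorta: just anterior to the spine, up to the diaphragm dome
  ar <- max(0.021 * ext[1] * s, 1.01 * max(sp[1:2]))
  labels <- paint_tube(labels, grid,
                       c(cx + 0.02 * ext[1] * s, cy - 0.115 * ext[2] * s),
                       c(ar, ar), 2,
                       c(0, 0.70 * ext[3]), organ_ids()[["aorta"]])

  # hepatic vessels: a portal-style tube plus two branches inside the
  # liver; radii never drop below one voxel so coarse grids keep them
  vid <- organ_ids()[["hepatic_vessel"]]
  vr1 <- max(0.018 * ext[1] * s, 1.01 * max(sp[1:2]))
  vr2 <- max(0.012 * ext[1] * s, 1.01 * max(sp[1:2]))
  vlab <- array(0L, dim = d)
  vlab <- paint_tube(vlab, grid, c(liver_center[1], liver_center[2]),
                     c(vr1, vr1), 2,
                     liver_center[3] + c(-0.7, 0.55) * liver_semi[3], vid)
  vlab <- paint_tube(vlab, grid,
                     c(liver_center[1] - 0.08 * ext[1] * s, liver_center[2]),
                     c(vr2, vr2), 2,
                     liver_center[3] + c(-0.35, 0.45) * liver_semi[3], vid,
                     tilt = c(-0.05, 0.03))
  vlab <- paint_tube(vlab, grid,
                     c(liver_center[1] + 0.02 * ext[1] * s,
                       liver_center[2] + 0.07 * ext[2] * s),
                     c(vr2, vr2), 2,
                     liver_center[3] + c(-0.45, 0.35) * liver_semi[3], vid,
                     tilt = c(0.04, -0.04))
  # vessels only where they sit inside the liver (precedence: vessel > liver)
  labels[vlab == vid & labels == organ_ids()[["liver"]]] <- vid

  vol <- organ_label_volume(labels, spacing = sp, organ_catalog = organ_ids())
  mandatory <- c("body", "lung_left", "lung_right", "liver", "hepatic_vessel",
                 "kidney_left", "kidney_right", "spleen", "stomach",
                 "spine", "aorta")
  counts <- vapply(mandatory, function(nm)
    sum(labels == organ_ids()[[nm]]), integer(1))
  if (any(counts == 0L))
    stop("configuration error: grid too small to place organs: ",
         paste(mandatory[counts == 0L], collapse = ", "))
  attr(vol, "config") <- config
  attr(vol, "seed") <- as.integer(seed)
  vol
}

#' Extract a binary organ mask
#'
#' @param phantom an [organ_label_volume()].
#' @param organ_ids integer ids or organ names; must all be in the catalog.
#'   An empty set yields an all-`FALSE` mask.
#' @return Logical 3D array, `TRUE` where the label is in `organ_ids`.
#' @export
extract_organ_mask <- function(phantom, organ_ids) {
  stopifnot(inherits(phantom, "organ_label_volume"))
  if (is.character(organ_ids)) {
    unknown <- setdiff(organ_ids, names(phantom$organ_catalog))
    if (length(unknown) > 0)
      stop("unknown organ name(s): ", paste(unknown, collapse = ", "))
    organ_ids <- phantom$organ_catalog[organ_ids]
  }
  organ_ids <- as.integer(organ_ids)
  unknown <- setdiff(organ_ids, phantom$organ_catalog)
  if (length(unknown) > 0)
    stop("unknown organ id(s): ", paste(unknown, collapse = ", "))
  array(phantom$labels %in% organ_ids, dim = dim(phantom$labels))
}
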
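# Respiratory deformation model. Two knobs drive the field: the amount of
# diaphragmatic motion (superior-inferior) and the amount of chest expansion
# (anterior-posterior). The exhaled state is the zero-displacement reference;
# the inhaled phantom is defined by warping the exhaled labels through the
# generated field, so ground-truth correspondence is exact by construction.

#' Respiratory motion parameters
#'
#' @param diaphragm_motion_mm peak superior-inferior diaphragm displacement
#'   (mm, >= 0).
#' @param chest_expansion_mm peak anterior chest-wall displacement (mm, >= 0).
#' @param state motion state the parameters describe; `"exhaled"` is the
#'   zero-displacement reference.
#' @return A list of class `motion_parameters`.
#' @export
motion_parameters <- function(diaphragm_motion_mm = 12,
                              chest_expansion_mm = 4,
                              state = c("inhaled", "exhaled")) {
  state <- match.arg(state)
  stopifnot(is.finite(diaphragm_motion_mm), diaphragm_motion_mm >= 0,
            is.finite(chest_expansion_mm), chest_expansion_mm >= 0)
  if (state == "exhaled" &&
      (diaphragm_motion_mm > 0 || chest_expansion_mm > 0))
    stop("the exhaled state is the zero-displacement reference")
  structure(list(diaphragm_motion_mm = diaphragm_motion_mm,
                 chest_expansion_mm = chest_expansion_mm,
                 state = state),
            class = "motion_parameters")
}

#' Generate a respiratory displacement field
#'
#' Diaphragm displacement is a superior-inferior translation weighted by a
#' smooth axial window centered on the diaphragm plane (the top of the
#' liver); chest expansion is an anterior displacement weighted by an
#' anterior-posterior window that vanishes at the posterior boundary. The
#' two components are blended additively and Gaussian-smoothed. The field
#' vanishes at the inferior and posterior volume boundaries and its maximum
#' magnitude never exceeds the configured amplitudes (up to smoothing, which
#' only averages).
#'
#' @param phantom exhaled-state [organ_label_volume()].
#' @param motion a [motion_parameters()] (state `"inhaled"`).
#' @param smooth_mm Gaussian smoothing of the field, mm.
#' @return A [displacement_field()] from `"exhaled"` to `"inhaled"`, usable
#'   directly with [warp_volume()] to produce the inhaled phantom.
#' @export
generate_respiratory_deformation <- function(phantom, motion,
                                             smooth_mm = 8) {
  stopifnot(inherits(phantom, "organ_label_volume"),
            inherits(motion, "motion_parameters"))
  d <- dim(phantom$labels)
  sp <- phantom$spacing
  ext <- (d - 1) * sp
  A <- motion$diaphragm_motion_mm
  B <- motion$chest_expansion_mm
  vecs <- array(0, dim = c(d, 3L))
  if (A == 0 && B == 0) {
    return(displacement_field(vecs, spacing = sp, origin = phantom$origin,
                              from_state = "exhaled", to_state = "exhaled"))
  }

  z <- (seq_len(d[3]) - 1) * sp[3]
  y <- (seq_len(d[2]) - 1) * sp[2]

  # diaphragm plane: top of the liver
  liver <- extract_organ_mask(phantom, c("liver", "hepatic_vessel"))
  z_dia <- if (any(liver)) {
    max(which(apply(liver, 3, any))) * sp[3]
  } else 0.6 * ext[3]
  sigma_d <- 0.18 * ext[3]
  wz <- exp(-0.5 * ((z - z_dia) / sigma_d)^2)
  # force exact zero at the inferior boundary
  wz <- wz * pmin(1, (z / (0.25 * ext[3])))^2

  # anterior window: zero at the posterior wall, ~1 at the anterior wall
  wy <- pmax(0, (y - 0.25 * ext[2]) / (0.75 * ext[2]))^2

  # pull-back convention: the inhaled volume samples the exhaled volume at
  # x + d(x). Inhalation moves the diaphragm inferiorly (tissue below the
  # diaphragm displaces toward -z), so the inhaled grid point looks
  # superiorly (+z) for its exhaled source; the anterior wall moves +y, so
  # the inhaled point looks posteriorly (-y).
  dz <- outer(rep(1, d[1] * d[2]), wz)          # (nx*ny, nz)
  vecs[, , , 3] <- array(A * dz, dim = d)
  dy <- rep(rep(wy, each = d[1]), times = d[3])
  vecs[, , , 2] <- array(-B * dy, dim = d)

  sig_vox <- smooth_mm / sp
  for (c3 in 2:3)
    vecs[, , , c3] <- smooth_gaussian(vecs[, , , c3], sig_vox)

  displacement_field(vecs, spacing = sp, origin = phantom$origin,
                     from_state = "exhaled", to_state = "inhaled")
}

#' Generate an exhaled/inhaled phantom pair with ground truth
#'
#' Convenience wrapper producing the exhaled phantom, the respiratory
#' displacement field, and the inhaled phantom obtained by warping the
#' exhaled labels through the field (nearest-neighbour), guaranteeing exact
#' voxel-for-voxel ground-truth correspondence.
#'
#' @inheritParams generate_phantom
#' @param motion a [motion_parameters()].
#' @return List with elements `exhaled`, `inhaled` (label volumes) and
#'   `field` (the exhaled-to-inhaled [displacement_field()]).
#' @export
generate_phantom_pair <- function(config = phantom_config(), seed = 1L,
                                  motion = motion_parameters()) {
  exhaled <- generate_phantom(config, seed)
  field <- generate_respiratory_deformation(exhaled, motion)
  inhaled <- warp_volume(exhaled, field, "nearest")
  list(exhaled = exhaled, inhaled = inhaled, field = field)
}
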
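# Modality simulation: label map -> CT / CBCT / MRI "phantom-style" volumes.
# CT/CBCT: per-organ attenuation at the simulated tube energy, converted to
# Hounsfield units; CBCT additionally gets a liver-centered cylindrical
# field-of-view mask. MRI: spoiled gradient-echo (VIBE) steady-state signal
# per organ with +-5% uniform jitter of T1/T2/rho. All modalities are then
# windowed and affinely normalized to [-1, 1].

#' Attenuation volume at a simulated tube energy
#'
#' Voxelwise lookup of the linear attenuation coefficient for each organ
#' label at one of the tabulated tube energies (no interpolation between
#' energies).
#'
#' @param phantom an [organ_label_volume()].
#' @param table a tissue property table (see [default_tissue_properties()]).
#' @param energy_keV one of [tube_energies()].
#' @return 3D numeric array of attenuation coefficients (1/cm).
#' @export
attenuation_volume <- function(phantom, table = default_tissue_properties(),
                               energy_keV = 100L) {
  stopifnot(inherits(phantom, "organ_label_volume"))
  if (!energy_keV %in% tube_energies())
    stop("energy must be one of ", paste(tube_energies(), collapse = ", "),
         " keV (no interpolation)")
  col <- paste0("mu_", energy_keV)
  ids <- sort(unique(as.vector(phantom$labels)))
  mu_by_id <- tissue_lookup(table, ids, col)
  lut <- stats::setNames(mu_by_id, ids)
  array(unname(lut[as.character(phantom$labels)]), dim = dim(phantom$labels))
}

#' Convert attenuation to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`, voxelwise.
#'
#' @param mu_volume 3D array of linear attenuation coefficients.
#' @param mu_water water attenuation at the same energy (> 0).
#' @return 3D array in HU.
#' @export
mu_to_hu <- function(mu_volume, mu_water) {
  if (!is.finite(mu_water) || mu_water <= 0)
    stop("`mu_water` must be strictly positive")
  1000 * (mu_volume - mu_water) / mu_water
}

#' Cone-beam field-of-view specification
#'
#' A cylinder (axial circle times z-extent) emulating the narrow C-arm
#' field of view focused on the liver.
#'
#' @param center physical (x, y, z) center in mm; `NULL` = liver centroid.
#' @param radius_mm in-plane radius (> 0).
#' @param z_extent_mm axial half-extent from the center; `Inf` keeps all
#'   slices.
#' @return A list of class `fov_spec`.
#' @export
fov_spec <- function(center = NULL, radius_mm = 110, z_extent_mm = Inf) {
  stopifnot(radius_mm > 0)
  structure(list(center = center, radius_mm = radius_mm,
                 z_extent_mm = z_extent_mm), class = "fov_spec")
}

#' Apply a cone-beam field-of-view mask
#'
#' Voxels outside a cylinder centered on the liver centroid (or an explicit
#' center) are set to the window floor, emulating the narrow cone-beam field
#' of view focused on the liver.
#'
#' @param volume a [modality_volume()] in native units with a `window` set,
#'   or any modality volume (then `floor_value` must be given).
#' @param liver_mask logical 3D array marking the liver (nonempty).
#' @param fov a [fov_spec()]; the center defaults to the liver centroid.
#' @param floor_value value assigned outside the FOV; defaults to the
#'   volume's window floor.
#' @return The masked [modality_volume()].
#' @export
apply_cbct_fov <- function(volume, liver_mask, fov = fov_spec(),
                           floor_value = NULL) {
  stopifnot(inherits(volume, "modality_volume"))
  arr <- volume$intensities
  if (!any(liver_mask)) stop("liver mask is empty")
  if (is.null(floor_value)) {
    if (is.null(volume$window)) stop("no window set; give `floor_value`")
    floor_value <- volume$window[1]
  }
  d <- dim(arr)
  sp <- volume$spacing
  if (is.null(fov$center)) {
    idx <- which(liver_mask, arr.ind = TRUE)
    fov$center <- (colMeans(idx) - 1) * sp + volume$origin
  }
  x <- volume$origin[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- volume$origin[2] + (seq_len(d[2]) - 1) * sp[2]
  z <- volume$origin[3] + (seq_len(d[3]) - 1) * sp[3]
  r2 <- outer((x - fov$center[1])^2, (y - fov$center[2])^2, "+")
  inside_xy <- r2 <= fov$radius_mm^2
  inside_z <- abs(z - fov$center[3]) <= fov$z_extent_mm
  keep <- array(as.vector(inside_xy), dim = d) &
    array(rep(inside_z, each = d[1] * d[2]), dim = d)
  arr[!keep] <- floor_value
  volume$intensities <- arr
  volume
}

#' VIBE parameters
#'
#' Acquisition parameters of the spoiled gradient-echo (VIBE) sequence.
#' Defaults follow a typical 3 T abdominal breath-hold protocol.
#'
#' @param TR repetition time, ms.
#' @param TE echo time, ms (`TR > TE >= 0`).
#' @param alpha flip angle, degrees (0..90).
#' @return A list of class `vibe_parameters`.
#' @export
vibe_parameters <- function(TR = 7.25, TE = 4.54, alpha = 10) {
  stopifnot(TR > TE, TE >= 0, alpha >= 0, alpha <= 90)
  structure(list(TR = TR, TE = TE, alpha = alpha), class = "vibe_parameters")
}

#' VIBE steady-state signal
#'
#' Spoiled gradient-echo signal
#' `SI = rho * sin(a) * (1 - exp(-TR/T1)) / (1 - cos(a) * exp(-TR/T1)) *
#' exp(-TE/T2)` with the flip angle `a` in degrees. Vectorized over the
#' tissue parameters.
#'
#' @param T1,T2 relaxation times, ms (> 0).
#' @param rho proton density, arbitrary units (> 0).
#' @param p a [vibe_parameters()].
#' @return Signal intensity (>= 0), same length as the tissue inputs.
#' @export
vibe_signal <- function(T1, T2, rho, p = vibe_parameters()) {
  stopifnot(inherits(p, "vibe_parameters"))
  if (any(T1 <= 0) || any(T2 <= 0) || any(rho <= 0))
    stop("T1, T2 and rho must be strictly positive")
  a <- p$alpha * pi / 180
  e1 <- exp(-p$TR / T1)
  rho * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-p$TE / T2)
}

#' Simulate a T1-weighted MRI phantom volume
#'
#' Each organ's `(T1, T2, rho)` is independently multiplied by
#' `Uniform(1 - jitter, 1 + jitter)` draws (one triple per organ per
#' volume) before evaluating the VIBE signal, emulating inter-subject tissue
#' variability. Deterministic given `seed`.
#'
#' @param phantom an [organ_label_volume()] (generate with `arms = TRUE`
#'   for MRI-style anatomy).
#' @param table tissue property table covering all catalog organs.
#' @param p a [vibe_parameters()].
#' @param jitter_frac uniform jitter fraction (default 0.05, i.e. +-5%).
#' @param seed integer seed for the jitter draws.
#' @return A [modality_volume()] with modality `"MRI"`, native signal units.
#' @export
mri_phantom <- function(phantom, table = default_tissue_properties(),
                        p = vibe_parameters(), jitter_frac = 0.05,
                        seed = 1L) {
  stopifnot(inherits(phantom, "organ_label_volume"), jitter_frac >= 0)
  ids <- sort(unique(as.vector(phantom$labels)))
  T1 <- tissue_lookup(table, ids, "T1_ms")
  T2 <- tissue_lookup(table, ids, "T2_ms")
  rho <- tissue_lookup(table, ids, "rho")
  set.seed(as.integer(seed))
  if (jitter_frac > 0) {
    n <- length(ids)
    jit <- matrix(stats::runif(3 * n, 1 - jitter_frac, 1 + jitter_frac),
                  nrow = n)
    T1 <- T1 * jit[, 1]; T2 <- T2 * jit[, 2]; rho <- rho * jit[, 3]
  }
  si <- vibe_signal(T1, T2, rho, p)
  # background carries (numerically) zero signal
  si[ids == 0L] <- 0
  lut <- stats::setNames(si, ids)
  arr <- array(unname(lut[as.character(phantom$labels)]),
               dim = dim(phantom$labels))
  modality_volume(arr, modality = "MRI", spacing = phantom$spacing,
                  origin = phantom$origin)
}

#' Default windowing intervals per modality
#'
#' CT `[-1024, 1500]` HU and CBCT `[-1024, 2000]` HU are fixed windows; MRI
#' uses the 10th and 90th percentile of the whole 3D array.
#'
#' @param modality `"CT"`, `"CBCT"` or `"MRI"`.
#' @return Numeric `(low, high)` window, or the string `"percentile"`.
#' @export
default_window <- function(modality) {
  switch(modality,
         CT = c(-1024, 1500),
         CBCT = c(-1024, 2000),
         MRI = "percentile",
         stop("unknown modality: ", modality))
}

#' Window and normalize a volume to \[-1, 1\]
#'
#' Clips intensities to the window and maps them affinely to \[-1, 1\].
#' With `window = "percentile"` the 10th/90th percentiles of the full 3D
#' array (background included) are used, as appropriate for MRI whose native
#' scale is arbitrary.
#'
#' @param volume a [modality_volume()].
#' @param window numeric `(low, high)`, `"percentile"`, or `NULL` to use
#'   [default_window()] for the volume's modality.
#' @param percentiles the two probabilities used by the percentile spec.
#' @return The normalized [modality_volume()] (`normalized = TRUE`, window
#'   recorded in native units).
#' @export
window_and_normalize <- function(volume, window = NULL,
                                 percentiles = c(0.1, 0.9)) {
  stopifnot(inherits(volume, "modality_volume"))
  if (is.null(window)) window <- default_window(volume$modality)
  arr <- volume$intensities
  if (identical(window, "percentile")) {
    window <- unname(stats::quantile(arr, percentiles, names = FALSE))
    if (window[1] >= window[2])
      stop("percentile windowing undefined: volume is (near) constant")
  }
  if (length(window) != 2L || window[1] >= window[2])
    stop("`window` must be (low, high) with low < high")
  arr <- pmin(pmax(arr, window[1]), window[2])
  arr <- (arr - window[1]) / (window[2] - window[1]) * 2 - 1
  volume$intensities <- arr
  volume$window <- as.numeric(window)
  volume$normalized <- TRUE
  volume
}

#' Simulate CT / CBCT / MRI phantom volumes
#'
#' One-call wrappers from a labeled phantom to a windowed, normalized
#' modality volume. CT and CBCT share the attenuation-to-HU path (the three
#' modalities of one phantom instance are co-registered by construction);
#' CBCT adds the liver-centered field-of-view mask.
#'
#' @param phantom an [organ_label_volume()].
#' @param table tissue property table.
#' @param energy_keV simulated tube energy (CT/CBCT).
#' @param fov a [fov_spec()] for CBCT.
#' @param normalize window/normalize to \[-1, 1\] (default `TRUE`).
#' @param ... passed to [mri_phantom()] (e.g. `seed`, `jitter_frac`).
#' @return A [modality_volume()].
#' @export
simulate_ct <- function(phantom, table = default_tissue_properties(),
                        energy_keV = 100L, normalize = TRUE) {
  mu <- attenuation_volume(phantom, table, energy_keV)
  hu <- mu_to_hu(mu, water_attenuation(table, energy_keV))
  vol <- modality_volume(hu, "CT", spacing = phantom$spacing,
                         origin = phantom$origin,
                         window = default_window("CT"))
  if (normalize) window_and_normalize(vol) else vol
}

#' @rdname simulate_ct
#' @export
simulate_cbct <- function(phantom, table = default_tissue_properties(),
                          energy_keV = 100L, fov = fov_spec(),
                          normalize = TRUE) {
  mu <- attenuation_volume(phantom, table, energy_keV)
  hu <- mu_to_hu(mu, water_attenuation(table, energy_keV))
  vol <- modality_volume(hu, "CBCT", spacing = phantom$spacing,
                         origin = phantom$origin,
                         window = default_window("CBCT"))
  liver <- extract_organ_mask(phantom, c("liver", "hepatic_vessel"))
  vol <- apply_cbct_fov(vol, liver, fov)
  if (normalize) window_and_normalize(vol) else vol
}

#' @rdname simulate_ct
#' @export
simulate_mri <- function(phantom, table = default_tissue_properties(),
                         normalize = TRUE, ...) {
  vol <- mri_phantom(phantom, table, ...)
  if (normalize) window_and_normalize(vol) else vol
}

#' Resample a volume to a new spacing
#'
#' Linear interpolation for scalar volumes, nearest-neighbour for label
#' volumes. Used to bring phantoms onto modality-specific grids.
#'
#' @param volume an [organ_label_volume()] or [modality_volume()].
#' @param new_spacing target spacing, mm.
#' @return Resampled volume of the same class.
#' @export
resample_volume <- function(volume, new_spacing) {
  arr <- volume_array(volume)
  d <- dim(arr)
  sp <- volume$spacing
  new_spacing <- rep_len(new_spacing, 3L)
  nd <- pmax(2L, as.integer(floor((d - 1) * sp / new_spacing)) + 1L)
  ax <- lapply(1:3, function(a) ((seq_len(nd[a]) - 1) * new_spacing[a]) /
                 sp[a] + 1)
  pts <- cbind(rep(ax[[1]], times = nd[2] * nd[3]),
               rep(rep(ax[[2]], each = nd[1]), times = nd[3]),
               rep(ax[[3]], each = nd[1] * nd[2]))
  interp <- if (inherits(volume, "organ_label_volume")) "nearest" else "linear"
  out <- array(sample_volume(arr, pts, interp), dim = nd)
  volume <- set_volume_array(volume, out)
  volume$spacing <- new_spacing
  volume
}
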
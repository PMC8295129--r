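# Tissue property tables: per-organ linear attenuation coefficients over the
# simulated tube-energy grid plus T1/T2/proton-density for MRI simulation.
# The shipped defaults are editable fixtures with literature-plausible
# values; the water row carries mu_water per energy for the HU conversion.

#' Simulated tube energies (keV)
#'
#' The attenuation table is tabulated on this grid; no interpolation between
#' energies is performed.
#'
#' @return Integer vector `c(90, 95, ..., 120)`.
#' @export
tube_energies <- function() seq(90L, 120L, by = 5L)

#' Default tissue property table
#'
#' One row per organ id of [organ_ids()] plus a `water` reference row.
#' Columns: `organ_id`, `name`, `mu_90` ... `mu_120` (linear attenuation,
#' 1/cm), `T1_ms`, `T2_ms`, `rho` (proton density, arbitrary units).
#' Attenuation decreases monotonically with energy; bone falls faster than
#' soft tissue, and the lung value is anchored so that lung tissue sits near
#' -760 HU, a typical digital-phantom initialization.
#'
#' @return A `data.frame` of class `tissue_property_table`.
#' @export
default_tissue_properties <- function() {
  # water linear attenuation (1/cm) on the energy grid
  mu_water <- c(0.1760, 0.1733, 0.1707, 0.1681, 0.1657, 0.1635, 0.1614)
  # ratio to water at 90 keV and at 120 keV; intermediate energies are
  # linear in energy between the two (bone hardens fastest)
  props <- list(
    #            r90    r120   T1     T2    rho
    background = c(0.0002, 0.0002,  1,     1,  0.001),
    body       = c(1.020, 1.018, 1412,  50,  0.70),
    lung_left  = c(0.240, 0.242, 1300,  30,  0.20),
    lung_right = c(0.240, 0.242, 1300,  30,  0.20),
    liver      = c(1.056, 1.052,  809,  34,  0.70),
    hepatic_vessel = c(1.058, 1.054, 1932, 275, 0.95),
    kidney_left  = c(1.032, 1.030, 1194,  76,  0.85),
    kidney_right = c(1.032, 1.030, 1194,  76,  0.85),
    spleen     = c(1.042, 1.040, 1328,  61,  0.85),
    stomach    = c(1.012, 1.010, 1100,  60,  0.80),
    spine      = c(1.700, 1.520,  586,  49,  0.40),
    aorta      = c(1.058, 1.054, 1932, 275,  0.95),
    arm_left   = c(1.020, 1.018, 1412,  50,  0.70),
    arm_right  = c(1.020, 1.018, 1412,  50,  0.70))
  ids <- organ_ids()
  en <- tube_energies()
  frac <- (en - 90) / 30
  rows <- lapply(names(props), function(nm) {
    p <- props[[nm]]
    ratio <- p[1] + (p[2] - p[1]) * frac
    c(list(organ_id = unname(ids[[nm]]), name = nm),
      stats::setNames(as.list(ratio * mu_water), paste0("mu_", en)),
      list(T1_ms = p[3], T2_ms = p[4], rho = p[5]))
  })
  water <- c(list(organ_id = NA_integer_, name = "water"),
             stats::setNames(as.list(mu_water), paste0("mu_", en)),
             list(T1_ms = 2500, T2_ms = 2000, rho = 1.0))
  tab <- do.call(rbind, lapply(c(rows, list(water)), as.data.frame))
  class(tab) <- c("tissue_property_table", "data.frame")
  validate_tissue_table(tab)
  tab
}

validate_tissue_table <- function(table) {
  en <- tube_energies()
  mu_cols <- paste0("mu_", en)
  stopifnot(all(c("organ_id", "name", mu_cols, "T1_ms", "T2_ms", "rho") %in%
                  names(table)))
  mu <- as.matrix(table[, mu_cols])
  if (any(mu < 0)) stop("attenuation coefficients must be >= 0")
  if (any(table$T1_ms <= 0) || any(table$T2_ms <= 0) || any(table$rho <= 0))
    stop("T1, T2 and rho must be strictly positive")
  invisible(table)
}

#' Read and write tissue property tables as CSV
#'
#' @param path CSV path; columns as in [default_tissue_properties()].
#' @return The table (read) or `path` invisibly (write).
#' @export
read_tissue_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("tissue_property_table", "data.frame")
  validate_tissue_table(tab)
  tab
}

#' @rdname read_tissue_table
#' @param table a tissue property table.
#' @export
write_tissue_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# Look up one property column for a vector of organ ids; errors name the
# missing organ.
tissue_lookup <- function(table, ids, column) {
  m <- match(ids, table$organ_id)
  if (anyNA(m)) {
    stop("tissue property `", column, "` missing for organ id(s): ",
         paste(unique(ids[is.na(m)]), collapse = ", "))
  }
  table[[column]][m]
}

#' Water attenuation at a simulated tube energy
#'
#' @param table a tissue property table containing a `water` row.
#' @param energy_keV one of [tube_energies()].
#' @return Linear attenuation of water (1/cm).
#' @export
water_attenuation <- function(table, energy_keV) {
  if (!energy_keV %in% tube_energies())
    stop("energy must be one of ", paste(tube_energies(), collapse = ", "),
         " keV (no interpolation)")
  row <- which(table$name == "water")
  if (length(row) != 1) stop("table has no unique `water` row")
  table[[paste0("mu_", energy_keV)]][row]
}
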
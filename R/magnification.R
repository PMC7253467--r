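#' Areal magnification ratio from retardation
#'
#' Centrifugal displacement spreads a ring of tissue born near the foveal
#' centre over a circle of radius equal to its displaced eccentricity, so
#' the available lateral area grows with the square of eccentricity. A
#' layer whose displacement is retarded by `R` at control eccentricity `E`
#' only reaches `E - R`, and its available area relative to control is
#' `((E - R) / E)^2`.
#'
#' @param E control eccentricity (µm, > 0).
#' @param retardation retardation (µm), `0 <= retardation <= E`.
#' @return Area ratio in `[0, 1]`; vectorized.
#' @examples
#' area_ratio(300, 252)  # 0.0256, prints as 0.03
#' @export
area_ratio <- function(E, retardation) {
  if (any(E <= 0)) stop("E must be > 0")
  if (any(retardation < 0)) stop("retardation must be >= 0")
  if (any(retardation > E)) {
    stop("retardation exceeds E: total blockage beyond the centre is not representable")
  }
  ((E - retardation) / E)^2
}

#' Volume magnification ratio
#'
#' Relative available volume: the product of the thickness ratio (axial)
#' and the area ratio (lateral). Computed from unrounded inputs; round to
#' 2 decimals only for reporting.
#'
#' @param thickness_ratio PG/C thickness ratio (>= 0).
#' @param area_ratio PG/C area ratio (>= 0).
#' @return Volume ratio; vectorized.
#' @export
volume_ratio <- function(thickness_ratio, area_ratio) {
  if (any(thickness_ratio < 0) || any(area_ratio < 0)) {
    stop("ratios must be >= 0")
  }
  thickness_ratio * area_ratio
}

#' Cone-pedicle geometry model
#'
#' Reference density and diameter of cone pedicles on the foveal slope of
#' a normal adult retina.
#'
#' @param density_per_mm2 pedicle density (cells/mm^2).
#' @param diameter_um average normal pedicle diameter (µm).
#' @return A list of class `pedicle_model`.
#' @export
pedicle_model <- function(density_per_mm2 = 25000, diameter_um = 6.3) {
  if (density_per_mm2 <= 0 || diameter_um <= 0) {
    stop("density and diameter must be > 0")
  }
  structure(list(density_per_mm2 = density_per_mm2,
                 diameter_um = diameter_um),
            class = "pedicle_model")
}

#' Minified cone-pedicle diameter under reduced areal magnification
#'
#' Keeping the number of pedicles fixed while the available area shrinks
#' by `area_ratio` forces each pedicle's footprint to shrink by the same
#' factor, so its diameter scales with the square root:
#' `d = d0 * sqrt(area_ratio)`.
#'
#' @param area_ratio available-area ratio (>= 0).
#' @param model a [pedicle_model()].
#' @return Diameter in µm; vectorized over `area_ratio`.
#' @examples
#' pedicle_diameter(area_ratio(300, 156))  # 3.0 um
#' @export
pedicle_diameter <- function(area_ratio, model = pedicle_model()) {
  if (any(area_ratio < 0)) stop("area ratio must be >= 0")
  model$diameter_um * sqrt(area_ratio)
}

#' Sphere-equivalent diameter ratio
#'
#' Models a structure's change in available space as the change in volume
#' of a sphere: a volume-like ratio `v` corresponds to a diameter ratio of
#' `v^(1/3)`. The caller chooses which ratio to cube-root (areal or
#' volumetric); the operation itself is agnostic.
#'
#' @param volume_like_ratio ratio (>= 0) to take the cube root of.
#' @return Diameter fraction; vectorized.
#' @examples
#' sphere_equivalent_diameter_ratio(area_ratio(300, 156))  # ~0.61
#' @export
sphere_equivalent_diameter_ratio <- function(volume_like_ratio) {
  if (any(volume_like_ratio < 0)) stop("ratio must be >= 0")
  volume_like_ratio^(1 / 3)
}

#' Retardation as a percentage of normal displacement
#'
#' Expresses retardation relative to a user-supplied normative centrifugal
#' displacement curve (for example a digitized ganglion-cell displacement
#' curve from the literature), interpolated linearly at `E`. Values above
#' 100% are permitted but flagged with a warning.
#'
#' @param retardation retardation (µm).
#' @param normal_curve data.frame with columns `eccentricity_um`
#'   (increasing) and `displacement_um` (>= 0).
#' @param E control eccentricity (µm), within the curve's range.
#' @return Percentage (0–100+).
#' @export
residual_displacement_pct <- function(retardation, normal_curve, E) {
  need <- c("eccentricity_um", "displacement_um")
  if (!is.data.frame(normal_curve) || !all(need %in% names(normal_curve))) {
    stop("normal_curve must have columns ", paste(need, collapse = ", "))
  }
  if (any(diff(normal_curve$eccentricity_um) <= 0)) {
    stop("normal_curve eccentricities must be increasing")
  }
  if (any(E < min(normal_curve$eccentricity_um)) ||
      any(E > max(normal_curve$eccentricity_um))) {
    stop("E outside the normal displacement curve's range")
  }
  normal <- approx(normal_curve$eccentricity_um,
                   normal_curve$displacement_um, xout = E)$y
  if (any(normal <= 0)) {
    stop("normal displacement at E must be > 0")
  }
  pct <- 100 * retardation / normal
  if (any(pct > 100)) {
    warning("retardation exceeds normal displacement (> 100%)")
  }
  pct
}

#' Build per-cell magnification records
#'
#' Joins retardation estimates with thickness ratios into the full model
#' table: one row per (group, layer, eccentricity) with area ratio, volume
#' ratio, and minified pedicle diameter.
#'
#' @param retardation data.frame with columns `group`, `layer`,
#'   `eccentricity_um`, `retardation_um`.
#' @param thickness_ratios data.frame with columns `group`, `layer`,
#'   `eccentricity_um`, `thickness_ratio`.
#' @param model a [pedicle_model()].
#' @return data.frame with the joined columns plus `area_ratio`,
#'   `volume_ratio`, `pedicle_diameter_um`.
#' @export
magnification_table <- function(retardation, thickness_ratios,
                                model = pedicle_model()) {
  rec <- merge(retardation[, c("group", "layer", "eccentricity_um",
                               "retardation_um")],
               thickness_ratios[, c("group", "layer", "eccentricity_um",
                                    "thickness_ratio")],
               by = c("group", "layer", "eccentricity_um"))
  if (nrow(rec) == 0L) stop("no (group, layer, eccentricity) cells in common")
  rec$area_ratio <- area_ratio(rec$eccentricity_um, rec$retardation_um)
  rec$volume_ratio <- volume_ratio(rec$thickness_ratio, rec$area_ratio)
  rec$pedicle_diameter_um <- pedicle_diameter(rec$area_ratio, model)
  rec[order(rec$group, rec$layer, rec$eccentricity_um), ]
}

#' Extremes of the volume ratio across layers at one eccentricity
#'
#' Minimum and maximum relative available volume over the layers measured
#' at a given control eccentricity, as integer percentages — the "volume
#' decrease ranged from a to b%" summary.
#'
#' @param records data.frame with columns `eccentricity_um` and
#'   `volume_ratio` (for example from [magnification_table()]).
#' @param E control eccentricity (µm).
#' @return Named numeric vector `c(min_pct, max_pct)`.
#' @examples
#' rec <- data.frame(eccentricity_um = 300,
#'                   volume_ratio = c(0.326, 0.153, 0.177))
#' volume_extremes_at(rec, 300)
#' @export
volume_extremes_at <- function(records, E) {
  rows <- records[records$eccentricity_um == E, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no records at eccentricity ", E)
  pct <- round(100 * rows$volume_ratio)
  c(min_pct = min(pct), max_pct = max(pct))
}
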
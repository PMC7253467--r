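#' Foveal developmental arrest (FDA) index
#'
#' Ratio of the combined HFL+ONL thickness to the summed IRL and OPL
#' thickness at the foveal centre. In a mature fovea the inner layers are
#' extruded from FC so the denominator is small and the index is high
#' (controls ~13); persisting inner-layer tissue drives it down (~5 or
#' below with structural immaturity). Homogeneous of degree 0: rescaling
#' all thicknesses leaves it unchanged.
#'
#' @param hfl_onl_t combined HFL+ONL thickness at FC (µm).
#' @param irl_t summed inner-retinal-layer (GCL+IPL+INL) thickness at FC
#'   (µm).
#' @param opl_t OPL thickness at FC (µm).
#' @return Dimensionless ratio; vectorized.
#' @examples
#' fda_index(170, 8, 5)   # control-like, ~13
#' fda_index(120, 84, 30) # severely immature, ~0.8
#' @export
fda_index <- function(hfl_onl_t, irl_t, opl_t) {
  if (any(hfl_onl_t < 0) || any(irl_t < 0) || any(opl_t < 0)) {
    stop("thicknesses must be >= 0")
  }
  denom <- irl_t + opl_t
  if (any(denom <= 0)) {
    stop("undefined index: IRL + OPL thickness must be > 0")
  }
  hfl_onl_t / denom
}

#' Preterm-to-control thickness ratio
#'
#' @param pg_thickness layer thickness in the preterm group (µm).
#' @param c_thickness layer thickness in controls (µm, > 0).
#' @return Ratio PG/C (raw double; round to 2 decimals for reporting);
#'   vectorized.
#' @export
thickness_ratio <- function(pg_thickness, c_thickness) {
  if (any(c_thickness <= 0)) {
    stop("control thickness must be > 0")
  }
  if (any(pg_thickness < 0)) {
    stop("thickness must be >= 0")
  }
  pg_thickness / c_thickness
}

#' Classify foveal maturity from the FDA index
#'
#' Low FDA indicates persisting inner-retinal tissue at FC. The default
#' cut-off of 5 with an "immature if index <= threshold" convention is
#' taken from the clear separation of group means (immature groups at or
#' below 5, mature groups well above); the boundary value itself counts as
#' immature.
#'
#' @param fda FDA index value(s), >= 0.
#' @param threshold classification cut-off.
#' @return Character vector, `"immature"` or `"mature"`.
#' @examples
#' classify_immaturity(c(2, 5, 13))
#' @export
classify_immaturity <- function(fda, threshold = 5) {
  if (any(fda < 0)) stop("FDA index must be >= 0")
  ifelse(fda <= threshold, "immature", "mature")
}

#' Lateral scaling factor from axial length
#'
#' Eccentricities measured on the scan are proportional to the distance
#' from the eye's second nodal point to the retina; a reduced-eye relation
#' places that nodal point 1.82 mm behind the cornea, so the scale factor
#' between an eye of axial length `axial_length` and a reference eye is
#' `(axial_length - 1.82) / (reference_axial_length - 1.82)`. Multiply
#' eccentricities by the factor to express them on the reference eye's
#' scale.
#'
#' @param axial_length axial length of the measured eye (mm, > 1.82).
#' @param reference_axial_length axial length of the reference eye (mm).
#' @param nodal_offset_mm nodal-point offset of the reduced eye (mm).
#' @return Dimensionless scale factor.
#' @examples
#' lateral_scaling(25.82, 23.82)  # ~1.0909
#' @export
lateral_scaling <- function(axial_length, reference_axial_length,
                            nodal_offset_mm = 1.82) {
  if (any(axial_length <= nodal_offset_mm) ||
      any(reference_axial_length <= nodal_offset_mm)) {
    stop("non-physical axial length: must exceed ", nodal_offset_mm, " mm")
  }
  (axial_length - nodal_offset_mm) /
    (reference_axial_length - nodal_offset_mm)
}

#' Foveal-centre metrics and FDA classification for a table of subjects
#'
#' Appends the FDA index and maturity class to a data.frame of
#' foveal-centre thicknesses.
#'
#' @param fc data.frame with columns `irlt_um`, `oplt_um`, `hfl_onlt_um`
#'   (other columns pass through).
#' @param threshold passed to [classify_immaturity()].
#' @return The input with `fda` and `class` columns appended.
#' @export
fc_metrics <- function(fc, threshold = 5) {
  need <- c("irlt_um", "oplt_um", "hfl_onlt_um")
  if (!all(need %in% names(fc))) {
    stop("fc must have columns ", paste(need, collapse = ", "))
  }
  fc$fda <- fda_index(fc$hfl_onlt_um, fc$irlt_um, fc$oplt_um)
  fc$class <- classify_immaturity(fc$fda, threshold)
  fc
}
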
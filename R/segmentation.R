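#' Locate the OPL reflectivity band in a search window
#'
#' Finds the hyperreflective OPL band inside a caller-supplied depth
#' window: the peak is the maximum reflectivity in the window (ties forming
#' a plateau are resolved to the plateau midpoint), and the inner and outer
#' troughs are the nearest local minima flanking the peak, searched outward
#' as far as the window edges. No anatomical inference is attempted; the
#' window is the caller's responsibility.
#'
#' @param profile a [reflectivity_profile()].
#' @param window numeric length-2 depth window (µm) within the profile's
#'   depth range, containing at least 5 samples.
#' @return An object of class `band_location`: list with `peak_depth_um`,
#'   `peak_reflectivity`, `inner_trough` and `outer_trough` (each a list
#'   with `depth_um`, `reflectivity`).
#' @examples
#' bands <- data.frame(layer = "OPL", inner_um = 140, outer_um = 160,
#'                     level = 0.7)
#' a <- synthesize_ascan(bands, edge_softness = 4)
#' locate_opl_band(a, c(100, 200))
#' @export
locate_opl_band <- function(profile, window) {
  stopifnot(inherits(profile, "reflectivity_profile"))
  d <- profile$samples$depth_um
  r <- profile$samples$reflectivity
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("window must be (min depth, max depth) with min < max")
  }
  if (window[1] < min(d) || window[2] > max(d)) {
    stop("window must lie within the profile depth range")
  }
  idx <- which(d >= window[1] & d <= window[2])
  if (length(idx) < 5L) stop("window must contain at least 5 samples")
  dw <- d[idx]
  rw <- r[idx]
  if (max(rw) - min(rw) <= .Machine$double.eps * 4) {
    stop("degenerate profile: window is flat")
  }
  peak_val <- max(rw)
  tied <- which(rw == peak_val)
  # A plateau of tied maxima is summarized by its midpoint.
  tied <- tied[seq_len(min(which(diff(c(tied, Inf)) > 1)))]
  peak_i <- tied[ceiling(length(tied) / 2)]
  if (min(tied) == 1L || max(tied) == length(rw)) {
    stop("band not found: no interior peak in window")
  }
  find_trough <- function(direction) {
    i <- peak_i
    repeat {
      j <- i + direction
      if (j < 1L || j > length(rw)) {
        # Window edge: accept it as the flanking minimum.
        return(i)
      }
      if (rw[j] > rw[i]) {
        return(i)
      }
      i <- j
    }
  }
  it <- find_trough(-1L)
  ot <- find_trough(1L)
  if (rw[it] >= peak_val || rw[ot] >= peak_val) {
    stop("band not found: no trough below the peak on a flank")
  }
  structure(
    list(
      peak_depth_um = mean(dw[tied]),
      peak_reflectivity = peak_val,
      peak_index = idx[peak_i],
      inner_trough = list(depth_um = dw[it], reflectivity = rw[it],
                          index = idx[it]),
      outer_trough = list(depth_um = dw[ot], reflectivity = rw[ot],
                          index = idx[ot])
    ),
    class = "band_location"
  )
}

#' @export
print.band_location <- function(x, ...) {
  cat(sprintf(
    "<band_location> peak %.3f at %g um; troughs %.3f at %g um / %.3f at %g um\n",
    x$peak_reflectivity, x$peak_depth_um,
    x$inner_trough$reflectivity, x$inner_trough$depth_um,
    x$outer_trough$reflectivity, x$outer_trough$depth_um
  ))
  invisible(x)
}

# First sub-sample crossing of `level` walking from the peak outward along
# one flank; linear interpolation between the bracketing samples.
.half_crossing <- function(d, r, from, to, level) {
  step <- if (to >= from) 1L else -1L
  i <- from
  while (i != to) {
    j <- i + step
    if ((r[i] >= level && r[j] < level) || (r[i] > level && r[j] <= level)) {
      frac <- (r[i] - level) / (r[i] - r[j])
      return(d[i] + frac * (d[j] - d[i]))
    }
    i <- j
  }
  NA_real_
}

#' OPL thickness by the half-height ("midway point") criterion
#'
#' Each OPL border is placed where reflectivity crosses the midway level
#' between the band's peak reflectivity and the flanking trough: the inner
#' border uses the hyporeflective trough on the INL side, the outer border
#' the trough on the HFL/ONL side. Crossings are located to sub-sample
#' precision by linear interpolation between adjacent samples (the OPL is
#' only a few pixels thick, so whole-pixel quantization is unacceptable).
#' Thickness is the depth difference of the two borders. Boundaries are
#' invariant to affine rescaling of the reflectivity axis.
#'
#' @param profile a [reflectivity_profile()].
#' @param band a `band_location` from [locate_opl_band()].
#' @return A list with `inner_um`, `outer_um`, `thickness_um`,
#'   `peak_depth_um`.
#' @examples
#' bands <- data.frame(layer = "OPL", inner_um = 140, outer_um = 160,
#'                     level = 0.7)
#' a <- synthesize_ascan(bands, edge_softness = 0)
#' b <- locate_opl_band(a, c(100, 200))
#' opl_thickness_midpoint(a, b)$thickness_um
#' @export
opl_thickness_midpoint <- function(profile, band) {
  stopifnot(inherits(profile, "reflectivity_profile"),
            inherits(band, "band_location"))
  d <- profile$samples$depth_um
  r <- profile$samples$reflectivity
  inner_level <- (band$peak_reflectivity + band$inner_trough$reflectivity) / 2
  outer_level <- (band$peak_reflectivity + band$outer_trough$reflectivity) / 2
  inner <- .half_crossing(d, r, band$peak_index, band$inner_trough$index,
                          inner_level)
  outer <- .half_crossing(d, r, band$peak_index, band$outer_trough$index,
                          outer_level)
  if (is.na(inner) || is.na(outer)) {
    stop("segmentation error: no half-height crossing on a flank")
  }
  list(inner_um = inner, outer_um = outer,
       thickness_um = outer - inner, peak_depth_um = band$peak_depth_um)
}

#' Segment the OPL from an A-scan in one call
#'
#' Convenience wrapper: [locate_opl_band()] then
#' [opl_thickness_midpoint()].
#'
#' @inheritParams locate_opl_band
#' @return As [opl_thickness_midpoint()].
#' @export
segment_opl <- function(profile, window) {
  opl_thickness_midpoint(profile, locate_opl_band(profile, window))
}
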
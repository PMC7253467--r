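#' Construct a retinal layer thickness profile
#'
#' A `layer_profile` holds the thickness of one retinal layer as a function
#' of temporal eccentricity for one subject or group mean. Eccentricity 0 is
#' the foveal centre (FC); all values are in micrometres.
#'
#' @param layer one of `"GCL_IPL"`, `"INL"`, `"OPL"`, `"HFL_ONL"`.
#' @param eccentricity_um strictly increasing eccentricities (µm, >= 0);
#'   at least 4 samples (spline fitting precondition).
#' @param thickness_um non-negative thicknesses (µm), same length.
#' @param subject_id subject or group-mean identifier.
#' @param group one of `"C"`, `"PG1"`, `"PG2"`, `"PG3"`, `"SYNTH"`.
#' @return An object of class `layer_profile`: a list with fields `layer`,
#'   `samples` (data.frame `eccentricity_um`, `thickness_um`), `subject_id`,
#'   `group`, and `side` (always `"temporal"`).
#' @examples
#' p <- layer_profile("INL", seq(0, 1200, 100), rep(30, 13))
#' p$samples[1:3, ]
#' @export
layer_profile <- function(layer, eccentricity_um, thickness_um,
                          subject_id = "mean", group = "SYNTH") {
  layer <- match.arg(layer, LAYERS)
  group <- match.arg(group, GROUPS)
  e <- as.numeric(eccentricity_um)
  t <- as.numeric(thickness_um)
  if (length(e) != length(t)) {
    stop("eccentricity_um and thickness_um must have the same length")
  }
  if (length(e) < 4L) {
    stop("a layer profile needs at least 4 samples")
  }
  if (anyNA(e) || anyNA(t)) {
    stop("layer profile samples must not contain NA")
  }
  if (any(e < 0)) {
    stop("eccentricities must be >= 0")
  }
  if (any(diff(e) <= 0)) {
    stop("eccentricities must be strictly increasing")
  }
  if (any(t < 0)) {
    stop("thickness values must be >= 0")
  }
  structure(
    list(
      layer = layer,
      samples = data.frame(eccentricity_um = e, thickness_um = t),
      subject_id = as.character(subject_id),
      group = group,
      side = "temporal"
    ),
    class = "layer_profile"
  )
}

#' @export
print.layer_profile <- function(x, ...) {
  e <- x$samples$eccentricity_um
  cat(sprintf(
    "<layer_profile> %s  %s/%s  %d samples on [%g, %g] um\n",
    x$layer, x$group, x$subject_id, nrow(x$samples), min(e), max(e)
  ))
  invisible(x)
}

#' @export
as.data.frame.layer_profile <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id,
    group = x$group,
    layer = x$layer,
    eccentricity_um = x$samples$eccentricity_um,
    thickness_um = x$samples$thickness_um
  )
}

is_layer_profile <- function(x) inherits(x, "layer_profile")
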
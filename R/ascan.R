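#' Construct an A-scan reflectivity profile
#'
#' Reflectivity (normalized to `[0, 1]`) versus depth at uniform axial
#' sampling. Synthetic profiles may carry their true band boundaries for
#' validation of the segmentation stage.
#'
#' @param depth_um strictly increasing depths (µm) at a uniform step.
#' @param reflectivity values in `[0, 1]`, same length.
#' @param bands optional data.frame of true band boundaries with columns
#'   `layer`, `inner_um`, `outer_um` (and optionally `level`).
#' @return An object of class `reflectivity_profile`: list with `samples`
#'   (data.frame `depth_um`, `reflectivity`), `step_um`, `bands`.
#' @export
reflectivity_profile <- function(depth_um, reflectivity, bands = NULL) {
  d <- as.numeric(depth_um)
  r <- as.numeric(reflectivity)
  if (length(d) != length(r)) stop("depth and reflectivity lengths differ")
  if (length(d) < 2L) stop("an A-scan needs at least 2 samples")
  steps <- diff(d)
  if (any(steps <= 0)) stop("depths must be strictly increasing")
  if (max(steps) - min(steps) > 1e-6 * mean(steps)) {
    stop("depths must be uniformly sampled")
  }
  if (any(r < -1e-12 | r > 1 + 1e-12)) {
    stop("reflectivity must lie within [0, 1]")
  }
  structure(
    list(samples = data.frame(depth_um = d,
                              reflectivity = pmin(pmax(r, 0), 1)),
         step_um = mean(steps), bands = bands),
    class = "reflectivity_profile"
  )
}

#' @export
print.reflectivity_profile <- function(x, ...) {
  d <- x$samples$depth_um
  cat(sprintf("<reflectivity_profile> %d samples, depth [%g, %g] um, step %g um\n",
              nrow(x$samples), min(d), max(d), x$step_um))
  if (!is.null(x$bands)) {
    cat(sprintf("  %d true band(s): %s\n", nrow(x$bands),
                paste(x$bands$layer, collapse = ", ")))
  }
  invisible(x)
}

# Unit band shape: 1 at the band centre, falling to 0 away from the band.
# Finite-width bands use error-function edges (a box convolved with a
# Gaussian of sd = softness, renormalized so the centre attains 1);
# zero-width bands degenerate to a pure Gaussian of sd = softness.
.band_bump <- function(d, inner, outer, softness) {
  if (outer > inner) {
    if (softness == 0) {
      return(as.numeric(d >= inner & d <= outer))
    }
    centre <- (inner + outer) / 2
    raw <- stats::pnorm((d - inner) / softness) -
      stats::pnorm((d - outer) / softness)
    peak <- stats::pnorm((centre - inner) / softness) -
      stats::pnorm((centre - outer) / softness)
    return(raw / peak)
  }
  if (softness == 0) {
    return(as.numeric(d == inner))
  }
  exp(-(d - inner)^2 / (2 * softness^2))
}

#' Synthesize a banded A-scan reflectivity profile
#'
#' Emulates the alternation of hyper- and hyporeflective retinal bands seen
#' in an OCT A-scan: each band contributes a smooth bump that attains its
#' reflectivity level at the band centre and decays at the edges over the
#' `edge_softness` scale (error-function edges; a zero-width band becomes a
#' Gaussian of that sd, whose full width at half maximum is
#' `2 * softness * sqrt(2 * log(2))`). A baseline and seeded Gaussian noise
#' are added and the result is clipped to `[0, 1]`. The true band
#' boundaries are stored on the returned profile.
#'
#' @param bands data.frame with columns `layer`, `inner_um`, `outer_um`,
#'   `level`; bands must be ordered by depth and non-overlapping
#'   (`inner_um == outer_um` is allowed and means a zero-width band).
#' @param edge_softness edge decay scale (µm, >= 0).
#' @param noise_sd reflectivity noise sd (a.u., >= 0).
#' @param seed RNG seed for the noise.
#' @param depth_range depth extent (µm) of the scan.
#' @param step_um axial sampling step (µm).
#' @param baseline background reflectivity level.
#' @return A [reflectivity_profile()] with `bands` attached.
#' @examples
#' bands <- data.frame(layer = "OPL", inner_um = 100, outer_um = 120,
#'                     level = 0.8)
#' a <- synthesize_ascan(bands, edge_softness = 2, noise_sd = 0.01, seed = 1)
#' @export
synthesize_ascan <- function(bands, edge_softness = 0, noise_sd = 0,
                             seed = NULL, depth_range = c(0, 300),
                             step_um = 1, baseline = 0.05) {
  need <- c("layer", "inner_um", "outer_um", "level")
  if (!is.data.frame(bands) || !all(need %in% names(bands))) {
    stop("bands must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (edge_softness < 0) stop("edge softness must be >= 0")
  if (any(bands$outer_um < bands$inner_um)) {
    stop("each band needs inner_um <= outer_um")
  }
  if (nrow(bands) > 1L) {
    o <- order(bands$inner_um)
    if (any(o != seq_len(nrow(bands)))) {
      stop("bands must be ordered by depth")
    }
    if (any(bands$inner_um[-1L] < bands$outer_um[-nrow(bands)])) {
      stop("bands overlap")
    }
  }
  d <- seq(depth_range[1], depth_range[2], by = step_um)
  r <- rep(baseline, length(d))
  for (i in seq_len(nrow(bands))) {
    r <- r + bands$level[i] *
      .band_bump(d, bands$inner_um[i], bands$outer_um[i], edge_softness)
  }
  if (noise_sd > 0) {
    r <- with_seed(seed, r + rnorm(length(r), sd = noise_sd))
  }
  reflectivity_profile(d, pmin(pmax(r, 0), 1), bands = bands)
}
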
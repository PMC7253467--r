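#' Default control-fovea shape parameters
#'
#' One set of four shape parameters per layer: thickness at the foveal
#' centre (`residual_um`), thickness at the rim plateau (`rim_um`), and the
#' centre and width (µm) of the sigmoidal transition between them. Defaults
#' emulate a mature adult fovea: inner retinal layers (GCL+IPL, INL) almost
#' extruded from FC (4 µm residual each, so summed IRL thickness at FC is
#' 8 µm), a thin OPL remnant (5 µm), and a thick central HFL+ONL hump
#' (170 µm) so that the modelled layers sum to 183 µm at FC and the FDA
#' index at FC is 170 / 13 ~ 13.
#'
#' @return Named list (one entry per layer) of lists with fields
#'   `residual_um`, `rim_um`, `centre_um`, `width_um`.
#' @export
control_shape_defaults <- function() {
  list(
    GCL_IPL = list(residual_um = 4, rim_um = 90, centre_um = 450,
                   width_um = 150),
    INL     = list(residual_um = 4, rim_um = 38, centre_um = 400,
                   width_um = 130),
    OPL     = list(residual_um = 5, rim_um = 28, centre_um = 350,
                   width_um = 120),
    HFL_ONL = list(residual_um = 170, rim_um = 60, centre_um = 400,
                   width_um = 150)
  )
}

# Normalized logistic transition: s(0) = 0, s(Inf) = 1, sigmoidal in between.
.sigmoid01 <- function(e, centre, width) {
  l <- stats::plogis((e - centre) / width)
  l0 <- stats::plogis(-centre / width)
  (l - l0) / (1 - l0)
}

# Noise-free control thickness at eccentricity e for one layer's shape.
.control_thickness <- function(e, shape) {
  shape$residual_um +
    (shape$rim_um - shape$residual_um) *
      .sigmoid01(e, shape$centre_um, shape$width_um)
}

#' Default synthetic eccentricity grid
#'
#' 0 to 1200 µm in 25 µm steps: covers the 300–900 µm analysis window with
#' margin for spline edge effects.
#'
#' @return Numeric vector of eccentricities (µm).
#' @export
default_grid <- function() seq(0, 1200, by = 25)

#' Generate a control layer-thickness profile
#'
#' The control fovea is modelled with a single smooth family per layer:
#' thickness runs from a central residual at FC to a rim plateau through a
#' normalized logistic transition, `t(e) = residual + (rim - residual) *
#' s(e)` with `s(0) = 0` and `s(e) -> 1`. For the inner layers
#' (`residual < rim`) this is a sigmoidal rise out of the pit; for HFL+ONL
#' (`residual > rim`) the same family yields a central hump decreasing
#' outward. Optional seeded Gaussian noise (truncated at 0) emulates
#' segmentation jitter.
#'
#' @param layer layer name.
#' @param shape shape parameters (`residual_um`, `rim_um`, `centre_um`,
#'   `width_um`); default from [control_shape_defaults()].
#' @param grid eccentricity grid (µm), strictly increasing.
#' @param noise_sd thickness noise standard deviation (µm, >= 0).
#' @param seed RNG seed for the noise, or `NULL` to use the current stream.
#' @param subject_id,group passed to [layer_profile()].
#' @return A [layer_profile()].
#' @examples
#' p <- make_control_profile("INL")
#' p$samples$thickness_um[1]   # central residual, 4 um
#' @export
make_control_profile <- function(layer,
                                 shape = control_shape_defaults()[[layer]],
                                 grid = default_grid(),
                                 noise_sd = 0, seed = NULL,
                                 subject_id = "control_mean", group = "C") {
  layer <- match.arg(layer, LAYERS)
  if (is.null(shape) || is.null(shape$width_um) || shape$width_um <= 0) {
    stop("configuration error: transition width must be > 0")
  }
  if (length(grid) == 0L) {
    stop("configuration error: empty eccentricity grid")
  }
  t <- .control_thickness(grid, shape)
  if (noise_sd > 0) {
    t <- with_seed(seed, pmax(0, t + rnorm(length(t), sd = noise_sd)))
  }
  layer_profile(layer, grid, t, subject_id = subject_id, group = group)
}

#' Apply a retardation warp to a control profile
#'
#' Produces a "preterm" profile whose cumulative thickness satisfies
#' `Cum_PG(e) = Cum_C(psi(e))`: the thickness is `t_PG(e) =
#' t_C(psi(e)) * psi'(e)`, a mass-preserving change of variables, so the
#' material that the mature fovea spreads out to `psi(e)` is packed into
#' `[0, e]`. The control thickness is evaluated through an interpolating
#' natural spline of its samples, held constant beyond the sampled range
#' (the rim plateau).
#'
#' @param control a [layer_profile()].
#' @param warp a [warp_spec()].
#' @param group group label for the output profile.
#' @param noise_sd,seed optional seeded Gaussian thickness noise
#'   (truncated at 0), applied after the warp.
#' @return A list with elements `profile` (the warped [layer_profile()]),
#'   `retardation` (function of control eccentricity `E` returning the
#'   ground truth `E - psi^{-1}(E)`), and `warp`.
#' @examples
#' ctrl <- make_control_profile("INL")
#' pg <- apply_retardation_warp(ctrl, warp_spec(150, 300))
#' pg$retardation(900)
#' @export
apply_retardation_warp <- function(control, warp, group = "SYNTH",
                                   noise_sd = 0, seed = NULL) {
  stopifnot(is_layer_profile(control))
  if (!inherits(warp, "warp_spec")) stop("invalid warp")
  e <- control$samples$eccentricity_um
  f <- splinefun(e, control$samples$thickness_um, method = "natural")
  emin <- min(e)
  emax <- max(e)
  t_c <- function(x) f(pmin(pmax(x, emin), emax))
  psi_e <- warp_psi(warp, e)
  if (any(diff(psi_e) <= 0)) stop("invalid warp: psi is not increasing")
  t_pg <- pmax(0, t_c(psi_e) * warp_psi_deriv(warp, e))
  if (noise_sd > 0) {
    t_pg <- with_seed(seed, pmax(0, t_pg + rnorm(length(t_pg), sd = noise_sd)))
  }
  profile <- layer_profile(control$layer, e, t_pg,
                           subject_id = paste0(group, "_mean"), group = group)
  list(
    profile = profile,
    retardation = function(E) true_retardation(warp, E),
    warp = warp
  )
}

#' Configure a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: the preterm-like groups
#' (label, warp, thickness-noise sd each), the control shape parameters per
#' layer, the eccentricity grid, the control-group noise sd, the control
#' eccentricities at which ground-truth retardation is tabulated, and the
#' seed that fully determines the output.
#'
#' @param groups list of group definitions, each a list with fields
#'   `label`, `warp` (a [warp_spec()], or `NULL` for a control-like group
#'   with no warp and no ground-truth rows), and `noise_sd` (µm, default 0).
#' @param shapes per-layer shape parameters; default
#'   [control_shape_defaults()].
#' @param grid eccentricity grid (µm); must cover at least `[0, 900]`.
#' @param control_noise_sd thickness noise sd for the control profiles (µm).
#' @param truth_eccentricities control eccentricities (µm) for the
#'   ground-truth table.
#' @param warped_layers layers subject to the retardation warp. Default:
#'   the displacement layers GCL+IPL, INL and OPL; HFL+ONL develops
#'   centripetally with the photoreceptors and is generated un-warped, so
#'   that central inner-layer persistence depresses the FDA index as it
#'   does in real immature foveas.
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = default_cohort_groups(),
                          shapes = control_shape_defaults(),
                          grid = default_grid(),
                          control_noise_sd = 0,
                          truth_eccentricities = c(300, 500, 700, 900),
                          warped_layers = c("GCL_IPL", "INL", "OPL"),
                          seed = 1L) {
  labels <- vapply(groups, function(g) as.character(g$label), character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate group labels: ", paste(labels[duplicated(labels)],
                                           collapse = ", "))
  }
  if ("C" %in% labels) {
    stop("the control group 'C' is always generated; do not list it in groups")
  }
  if (length(grid) == 0L || min(grid) > 0 || max(grid) < 900) {
    stop("configuration error: grid must cover [0, 900] um")
  }
  for (g in groups) {
    if (!is.null(g$warp) && !inherits(g$warp, "warp_spec")) {
      stop("group '", g$label, "': warp must be a warp_spec or NULL")
    }
  }
  warped_layers <- match.arg(warped_layers, LAYERS, several.ok = TRUE)
  structure(
    list(groups = groups, shapes = shapes, grid = grid,
         control_noise_sd = control_noise_sd,
         truth_eccentricities = truth_eccentricities,
         warped_layers = warped_layers,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default preterm-like group definitions
#'
#' Three groups of increasing displacement blockage, calibrated to the
#' clinical grading's anchors. The warp's central compression factor is
#' `psi'(0) = 1 + r_max / lambda`, which multiplies the inner-layer
#' thickness at FC, so `(r_max, lambda)` are chosen to reproduce both the
#' published foveal-centre IRL persistence (summed IRL thickness ~9, 23
#' and 83 µm against a control of 8 µm) and retardation within the
#' 300–900 µm window inside each group's published range: PG1 (60, 600)
#' gives ~20–45 µm, PG2 (160, 85) ~135–160 µm, PG3 (330, 35) ~250–330 µm.
#'
#' @param noise_sd thickness noise sd (µm) applied to every group.
#' @return A list suitable for the `groups` argument of [cohort_config()].
#' @export
default_cohort_groups <- function(noise_sd = 0) {
  list(
    list(label = "PG1", warp = warp_spec(60, 600), noise_sd = noise_sd),
    list(label = "PG2", warp = warp_spec(160, 85), noise_sd = noise_sd),
    list(label = "PG3", warp = warp_spec(330, 35), noise_sd = noise_sd)
  )
}

#' Generate a synthetic cohort with known retardation ground truth
#'
#' Generates one control profile per layer plus, for every configured
#' group, the retardation-warped counterpart, and tabulates the analytic
#' ground-truth retardation at the configured control eccentricities.
#' The seed in the config fully determines the profiles; the ground truth
#' is analytic and independent of the seed.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `profiles` (named list of
#'   [layer_profile()]s, names `<group>.<layer>`), `data` (the same in long
#'   data.frame form, columns `subject_id`, `group`, `layer`,
#'   `eccentricity_um`, `thickness_um`), `truth` (data.frame `group`,
#'   `layer`, `eccentricity_um`, `true_retardation_um`), and `config`.
#' @examples
#' ch <- generate_cohort(cohort_config(seed = 7))
#' head(ch$truth)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- list()
  truth <- list()
  # Stable per-(group, layer) sub-seeds: output does not depend on the
  # order in which profiles are generated.
  sub_seed <- function(gi, li) (config$seed * 1000L + gi * 10L + li) %% .Machine$integer.max

  for (li in seq_along(LAYERS)) {
    layer <- LAYERS[li]
    ctrl <- make_control_profile(
      layer, shape = config$shapes[[layer]], grid = config$grid,
      noise_sd = config$control_noise_sd, seed = sub_seed(0L, li),
      subject_id = "C_mean", group = "C"
    )
    profiles[[paste("C", layer, sep = ".")]] <- ctrl
    # Warps act on the noise-free control shape; noise is per-group.
    ctrl_clean <- make_control_profile(
      layer, shape = config$shapes[[layer]], grid = config$grid,
      subject_id = "C_mean", group = "C"
    )
    for (gi in seq_along(config$groups)) {
      g <- config$groups[[gi]]
      glabel <- as.character(g$label)
      ggroup <- if (glabel %in% GROUPS) glabel else "SYNTH"
      noise_sd <- if (is.null(g$noise_sd)) 0 else g$noise_sd
      if (is.null(g$warp) || !(layer %in% config$warped_layers)) {
        prof <- make_control_profile(
          layer, shape = config$shapes[[layer]], grid = config$grid,
          noise_sd = noise_sd, seed = sub_seed(gi, li),
          subject_id = paste0(glabel, "_mean"), group = ggroup
        )
      } else {
        warped <- apply_retardation_warp(
          ctrl_clean, g$warp, group = ggroup,
          noise_sd = noise_sd, seed = sub_seed(gi, li)
        )
        prof <- warped$profile
        truth[[length(truth) + 1L]] <- data.frame(
          group = glabel, layer = layer,
          eccentricity_um = config$truth_eccentricities,
          true_retardation_um = true_retardation(g$warp,
                                                 config$truth_eccentricities)
        )
      }
      prof$subject_id <- paste0(glabel, "_mean")
      profiles[[paste(glabel, layer, sep = ".")]] <- prof
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(group = character(), layer = character(),
               eccentricity_um = numeric(), true_retardation_um = numeric())
  data <- do.call(rbind, lapply(profiles, as.data.frame))
  rownames(data) <- NULL
  list(profiles = profiles, data = data, truth = truth, config = config)
}
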
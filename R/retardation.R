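#' Fit a smooth thickness-vs-eccentricity function
#'
#' Fits a cubic spline to the samples of a layer profile. With
#' `smoothing = 0` (the default) the spline interpolates the samples
#' (natural cubic spline); a value in `(0, 1]` is passed to
#' [stats::smooth.spline()] as `spar`; `smoothing = "gcv"` lets
#' `smooth.spline` choose the penalty by generalized cross-validation,
#' which is the appropriate setting for noisy per-sample data.
#'
#' @param profile a [layer_profile()].
#' @param smoothing `0`, a `spar` value in `(0, 1]`, or `"gcv"`.
#' @return A function of eccentricity (µm), C1 on the sampled domain,
#'   carrying a `"domain"` attribute `c(min, max)` of the sampled
#'   eccentricities. Values are *not* clipped at zero here; integration
#'   clips.
#' @examples
#' p <- make_control_profile("INL")
#' f <- fit_thickness_spline(p)
#' f(c(0, 300, 900))
#' @export
fit_thickness_spline <- function(profile, smoothing = 0) {
  stopifnot(is_layer_profile(profile))
  e <- profile$samples$eccentricity_um
  t <- profile$samples$thickness_um
  if (length(e) < 4L) stop("fit error: need at least 4 samples")
  if (identical(smoothing, "gcv")) {
    sm <- smooth.spline(e, t)
    f <- function(x) predict(sm, x)$y
  } else if (is.numeric(smoothing) && length(smoothing) == 1L &&
             smoothing == 0) {
    f <- splinefun(e, t, method = "natural")
  } else if (is.numeric(smoothing) && length(smoothing) == 1L &&
             smoothing > 0) {
    sm <- smooth.spline(e, t, spar = smoothing)
    f <- function(x) predict(sm, x)$y
  } else {
    stop("smoothing must be 0, a spar value > 0, or \"gcv\"")
  }
  attr(f, "domain") <- range(e)
  f
}

#' Cumulative layer thickness from the foveal centre outward
#'
#' Integrates the (zero-clipped) fitted thickness function from
#' eccentricity 0 to `E_max`, producing the cumulative curve whose
#' horizontal displacement between groups measures retardation. If the
#' profile's samples start above eccentricity 0, the innermost sample value
#' is extended to 0 as a constant. The integral is accumulated on a fine
#' uniform grid (trapezoid rule, default step 0.25 µm), which doubles as
#' the curve's monotone tabulated representation for inversion.
#'
#' @param profile a [layer_profile()].
#' @param E_max upper integration limit (µm); must lie within the fitted
#'   domain.
#' @param smoothing passed to [fit_thickness_spline()].
#' @param step tabulation step (µm).
#' @return An object of class `cumulative_curve`: list with `layer`,
#'   `group`, `grid` (eccentricities, µm), `values` (cumulative area,
#'   µm^2; `values[1] == 0`, non-decreasing), `E_max`, `step`.
#' @examples
#' p <- make_control_profile("INL")
#' cc <- cumulative_curve(p, E_max = 900)
#' eval_cumulative(cc, c(300, 900))
#' @export
cumulative_curve <- function(profile, E_max, smoothing = 0, step = 0.25) {
  stopifnot(is_layer_profile(profile))
  f <- fit_thickness_spline(profile, smoothing)
  dom <- attr(f, "domain")
  if (!is.numeric(E_max) || length(E_max) != 1L || E_max <= 0 ||
      E_max > dom[2] + 1e-9) {
    stop("range error: E_max must lie in (0, ", dom[2], "]")
  }
  grid <- seq(0, E_max, by = step)
  if (tail(grid, 1L) < E_max) grid <- c(grid, E_max)
  vals <- pmax(f(pmax(grid, dom[1])), 0)   # constant extension below dom[1]
  cum <- c(0, cumsum((vals[-1L] + vals[-length(vals)]) / 2 * diff(grid)))
  structure(
    list(layer = profile$layer, group = profile$group,
         grid = grid, values = cum, E_max = E_max, step = step),
    class = "cumulative_curve"
  )
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("<cumulative_curve> %s/%s on [0, %g] um, total %.1f um^2\n",
              x$layer, x$group, x$E_max, tail(x$values, 1L)))
  invisible(x)
}

#' Evaluate a cumulative curve
#'
#' Linear interpolation on the tabulated grid.
#'
#' @param curve a [cumulative_curve()].
#' @param e eccentricities (µm) within `[0, E_max]`.
#' @return Cumulative values (µm^2).
#' @export
eval_cumulative <- function(curve, e) {
  stopifnot(inherits(curve, "cumulative_curve"))
  if (any(e < 0 | e > curve$E_max + 1e-9)) {
    stop("range error: eccentricity outside [0, E_max]")
  }
  approx(curve$grid, curve$values, xout = pmin(e, curve$E_max))$y
}

# Smallest eccentricity at which `curve` reaches `target` (monotone
# inversion; plateaus resolve to their smallest eccentricity).
.invert_cumulative <- function(curve, target) {
  v <- curve$values
  if (target > v[length(v)]) {
    stop("unreachable value: target exceeds the curve's total at E_max")
  }
  if (target <= v[1L]) {
    return(curve$grid[1L])
  }
  i <- which(v >= target)[1L]
  # v[i - 1] < target <= v[i], so the segment is strictly increasing here.
  frac <- (target - v[i - 1L]) / (v[i] - v[i - 1L])
  curve$grid[i - 1L] + frac * (curve$grid[i] - curve$grid[i - 1L])
}

#' Retardation at one control eccentricity
#'
#' The displacement-retardation measurement: pick a control eccentricity
#' `E`, read the control group's cumulative thickness there, and find the
#' smallest eccentricity `e*` at which the preterm group's cumulative curve
#' reaches the same value. Retardation is the horizontal distance
#' `E - e*`; the residual displacement is `e*` itself.
#'
#' @param cum_control,cum_pg [cumulative_curve()]s for the same layer.
#' @param E control eccentricity (µm), within both curves' domains.
#' @return One-row data.frame with columns `layer`, `group`,
#'   `eccentricity_um`, `retardation_um`, `residual_um`, `status`.
#' @examples
#' ctrl <- make_control_profile("INL")
#' pg <- apply_retardation_warp(ctrl, warp_spec(150, 300), group = "PG2")
#' cc <- cumulative_curve(ctrl, 1200)
#' cp <- cumulative_curve(pg$profile, 1200)
#' retardation_at(cc, cp, 900)
#' @export
retardation_at <- function(cum_control, cum_pg, E) {
  stopifnot(inherits(cum_control, "cumulative_curve"),
            inherits(cum_pg, "cumulative_curve"))
  if (cum_control$layer != cum_pg$layer) {
    stop("curves must describe the same layer")
  }
  if (E < 0 || E > cum_control$E_max + 1e-9 || E > cum_pg$E_max + 1e-9) {
    stop("range error: E outside a curve domain")
  }
  target <- eval_cumulative(cum_control, E)
  e_star <- .invert_cumulative(cum_pg, target)
  data.frame(
    layer = cum_pg$layer, group = cum_pg$group,
    eccentricity_um = E,
    retardation_um = E - e_star,
    residual_um = e_star,
    status = "ok"
  )
}

#' Retardation at a set of control eccentricities
#'
#' Applies [retardation_at()] per eccentricity; failures (for example an
#' unreachable cumulative value) are recorded per eccentricity in the
#' `status` column rather than aborting the profile.
#'
#' @inheritParams retardation_at
#' @param eccentricities control eccentricities (µm); default the analysis
#'   grid 300, 500, 700, 900.
#' @return data.frame, one row per eccentricity (possibly zero rows).
#' @export
retardation_profile <- function(cum_control, cum_pg,
                                eccentricities = c(300, 500, 700, 900)) {
  rows <- lapply(eccentricities, function(E) {
    tryCatch(retardation_at(cum_control, cum_pg, E),
             error = function(err) data.frame(
               layer = cum_pg$layer, group = cum_pg$group,
               eccentricity_um = E,
               retardation_um = NA_real_, residual_um = NA_real_,
               status = conditionMessage(err)
             ))
  })
  if (length(rows) == 0L) {
    return(data.frame(layer = character(), group = character(),
                      eccentricity_um = numeric(),
                      retardation_um = numeric(), residual_um = numeric(),
                      status = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize retardation over the foveal window
#'
#' Mean, minimum and maximum retardation over all (layer x eccentricity)
#' cells inside an eccentricity window, the convention used for the
#' group-level "average retardation within the foveal region".
#'
#' @param estimates data.frame of retardation estimates (rows from
#'   [retardation_at()] / [retardation_profile()], possibly several
#'   layers).
#' @param window inclusive eccentricity window (µm), default
#'   `c(300, 900)`.
#' @return A list of class `group_summary`: `group`, `window`, `mean_um`
#'   (raw), `mean_um_reported` (rounded to integer µm), `min_um`,
#'   `max_um`, `n_cells`.
#' @export
group_summary <- function(estimates, window = c(300, 900)) {
  stopifnot(is.data.frame(estimates))
  keep <- estimates$eccentricity_um >= window[1] &
    estimates$eccentricity_um <= window[2]
  if ("status" %in% names(estimates)) {
    keep <- keep & estimates$status == "ok"
  }
  est <- estimates[keep, , drop = FALSE]
  if (nrow(est) == 0L) {
    stop("no usable estimates within the window")
  }
  r <- est$retardation_um
  structure(
    list(group = paste(unique(est$group), collapse = "+"),
         window = window,
         mean_um = mean(r),
         mean_um_reported = round(mean(r)),
         min_um = min(r), max_um = max(r),
         n_cells = length(r)),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "<group_summary> %s, %g-%g um: mean %d um (range %g-%g), n = %d\n",
    x$group, x$window[1], x$window[2], x$mean_um_reported,
    x$min_um, x$max_um, x$n_cells
  ))
  invisible(x)
}

#' Estimate retardation for every group and layer of a cohort
#'
#' Builds the control and group cumulative curves per layer from a
#' synthetic or measured cohort and runs [retardation_profile()] for every
#' (group, layer). The inner-retinal layers and OPL carry the displacement
#' signal; HFL+ONL is excluded by default, matching the layers analysed
#' for retardation.
#'
#' @param cohort a cohort as returned by [generate_cohort()], or any list
#'   with a `profiles` element of [layer_profile()]s named
#'   `<group>.<layer>`.
#' @param eccentricities control eccentricities (µm).
#' @param smoothing passed to [cumulative_curve()].
#' @param layers layers to analyse.
#' @param E_max upper integration limit (µm); default the top of the
#'   sampled grid.
#' @return data.frame with columns `group`, `layer`, `eccentricity_um`,
#'   `retardation_um`, `residual_um`, `status`.
#' @export
cohort_retardation <- function(cohort,
                               eccentricities = c(300, 500, 700, 900),
                               smoothing = 0,
                               layers = c("GCL_IPL", "INL", "OPL"),
                               E_max = NULL) {
  profiles <- cohort$profiles
  groups <- unique(vapply(strsplit(names(profiles), ".", fixed = TRUE),
                          `[[`, character(1), 1L))
  groups <- setdiff(groups, "C")
  rows <- list()
  for (layer in layers) {
    ctrl <- profiles[[paste("C", layer, sep = ".")]]
    if (is.null(ctrl)) stop("cohort has no control profile for ", layer)
    emax <- if (is.null(E_max)) max(ctrl$samples$eccentricity_um) else E_max
    cum_c <- cumulative_curve(ctrl, emax, smoothing = smoothing)
    for (g in groups) {
      prof <- profiles[[paste(g, layer, sep = ".")]]
      if (is.null(prof)) next
      cum_g <- cumulative_curve(prof, emax, smoothing = smoothing)
      est <- retardation_profile(cum_c, cum_g, eccentricities)
      est$group <- g
      rows[[length(rows) + 1L]] <- est
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("group", "layer", "eccentricity_um", "retardation_um",
          "residual_um", "status")]
}
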
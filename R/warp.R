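#' Specify a retardation warp
#'
#' A warp models arrested centrifugal displacement as a smooth, strictly
#' increasing map of eccentricity, `psi(e) >= e`, `psi(0) = 0`: material
#' that would normally sit at eccentricity `psi(e)` in a mature fovea is
#' found at `e` in the retarded one. The induced ground-truth retardation at
#' a control eccentricity `E` is `E - psi^{-1}(E)`.
#'
#' Two families are available:
#' * `"saturating_exponential"`: `psi(e) = e + r_max * (1 - exp(-e / lambda))`
#'   — large fractional blockage centrally, saturating to an `r_max` shift
#'   peripherally.
#' * `"linear_capped"`: `psi(e) = e + r_max * min(e / lambda, 1)` — a linear
#'   ramp up to `e = lambda`, then a constant shift.
#'
#' @param r_max asymptotic retardation (µm, >= 0).
#' @param lambda spatial scale of the warp (µm, > 0).
#' @param form warp family.
#' @return An object of class `warp_spec`.
#' @examples
#' w <- warp_spec(r_max = 150, lambda = 300)
#' warp_psi(w, c(0, 300, 900))
#' true_retardation(w, c(300, 900))
#' @export
warp_spec <- function(r_max, lambda,
                      form = c("saturating_exponential", "linear_capped")) {
  form <- match.arg(form)
  if (!is.numeric(r_max) || length(r_max) != 1L || is.na(r_max) || r_max < 0) {
    stop("invalid warp: r_max must be a single number >= 0")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda <= 0) {
    stop("invalid warp: lambda must be a single number > 0")
  }
  structure(list(r_max = r_max, lambda = lambda, form = form),
            class = "warp_spec")
}

#' @export
print.warp_spec <- function(x, ...) {
  cat(sprintf("<warp_spec> %s  r_max = %g um, lambda = %g um\n",
              x$form, x$r_max, x$lambda))
  invisible(x)
}

#' Evaluate a warp, its derivative, and its inverse
#'
#' `warp_psi()` maps retarded eccentricity to the corresponding mature
#' eccentricity; `warp_psi_deriv()` is its first derivative (the local
#' lateral compression factor); `warp_psi_inverse()` solves `psi(x) = y`.
#' The inverse is closed form for `linear_capped` and obtained by bracketed
#' root finding (tolerance 1e-10 µm) for `saturating_exponential`.
#'
#' @param warp a [warp_spec()].
#' @param e,y eccentricities (µm, >= 0); vectorized.
#' @return Numeric vector of the same length as the input.
#' @export
warp_psi <- function(warp, e) {
  stopifnot(inherits(warp, "warp_spec"))
  switch(warp$form,
    saturating_exponential = e + warp$r_max * (1 - exp(-e / warp$lambda)),
    linear_capped = e + warp$r_max * pmin(e / warp$lambda, 1)
  )
}

#' @rdname warp_psi
#' @export
warp_psi_deriv <- function(warp, e) {
  stopifnot(inherits(warp, "warp_spec"))
  switch(warp$form,
    saturating_exponential =
      1 + (warp$r_max / warp$lambda) * exp(-e / warp$lambda),
    linear_capped = ifelse(e < warp$lambda, 1 + warp$r_max / warp$lambda, 1)
  )
}

#' @rdname warp_psi
#' @export
warp_psi_inverse <- function(warp, y) {
  stopifnot(inherits(warp, "warp_spec"))
  if (any(y < 0)) stop("eccentricities must be >= 0")
  if (warp$r_max == 0) {
    return(y)
  }
  if (warp$form == "linear_capped") {
    knee <- warp$lambda + warp$r_max       # psi(lambda)
    return(ifelse(y <= knee,
                  y * warp$lambda / (warp$lambda + warp$r_max),
                  y - warp$r_max))
  }
  vapply(y, function(yi) {
    if (yi == 0) return(0)
    lo <- max(0, yi - warp$r_max)
    uniroot(function(x) warp_psi(warp, x) - yi,
            lower = lo, upper = yi, tol = 1e-10)$root
  }, numeric(1))
}

#' Ground-truth retardation of a warp
#'
#' The retardation a perfect estimator should recover at control
#' eccentricity `E`: `E - psi^{-1}(E)`. Non-negative, and non-decreasing in
#' `r_max` for fixed `E`.
#'
#' @param warp a [warp_spec()].
#' @param E control eccentricities (µm); vectorized.
#' @return Retardation in µm, same length as `E`.
#' @export
true_retardation <- function(warp, E) {
  E - warp_psi_inverse(warp, E)
}
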
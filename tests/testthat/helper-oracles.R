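# Brute-force retardation oracle: tabulate both cumulative curves on a
# fine uniform grid by direct trapezoid accumulation of the interpolating
# splines, then scan for the first grid point where the preterm cumulative
# reaches the control value at E. Independent of the package's tabulation,
# inversion and interpolation code paths.
oracle_retardation <- function(control, pg, E, step = 0.5) {
  g <- seq(0, max(control$samples$eccentricity_um), by = step)
  cum_of <- function(p) {
    f <- stats::splinefun(p$samples$eccentricity_um, p$samples$thickness_um,
                          method = "natural")
    v <- pmax(f(pmax(g, min(p$samples$eccentricity_um))), 0)
    c(0, cumsum((v[-1] + v[-length(v)]) / 2 * step))
  }
  cc <- cum_of(control)
  cp <- cum_of(pg)
  target <- cc[match(E, g)]
  stopifnot(!is.na(target))
  i <- which(cp >= target)[1]
  E - g[i]
}

# Constant-thickness profile on the default grid.
flat_profile <- function(thickness, layer = "INL", group = "SYNTH",
                         grid = seq(0, 1200, by = 25)) {
  layer_profile(layer, grid, rep(thickness, length(grid)), group = group)
}

# Noise-free logistic sigmoid used as a known smooth truth.
sigmoid_truth <- function(e, lo = 4, hi = 40, centre = 450, width = 150) {
  lo + (hi - lo) * stats::plogis((e - centre) / width)
}
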
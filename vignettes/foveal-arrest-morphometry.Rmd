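---
title: "Quantifying arrested foveal development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arrested foveal development: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovearrest)
```

## The measurement problem

A mature human fovea is excavated: during development the inner retinal
layers (GCL+IPL and INL, collectively IRL) and the outer plexiform layer
(OPL) are displaced centrifugally from the foveal centre (FC) toward the
foveal rim, while photoreceptor-related tissue (Henle fibre layer +
outer nuclear layer, HFL+ONL) packs in centripetally. In adults born
preterm this centrifugal displacement can be arrested, leaving
inner-layer tissue over FC and a shallow pit. Two questions drive this
package: *how far does displacement lag in each layer*, and *how much
lateral space do cells and synaptic networks lose as a consequence*.

The raw observable is, per layer and group, a thickness-vs-eccentricity
profile along the temporal meridian (µm vs µm, eccentricity 0 at FC).
All distances in the package are micrometres.

## Retardation from cumulative thickness curves

A layer's cumulative thickness, `Cum(E) = ∫₀ᴱ t(e) de`, is invariant
under any displacement that conserves layer mass: tissue that moves
outward carries its cumulative total with it. If a preterm layer's
displacement lags the control's, its cumulative curve is shifted toward
the centre, and the lag at control eccentricity `E` is read off
horizontally:

`R(E) = E − e*`, where `e*` is the smallest eccentricity with
`Cum_PG(e*) = Cum_C(E)`.

Implementation choices:

* **Spline family.** Thickness profiles are fitted with a natural cubic
  interpolating spline by default (`smoothing = 0`); a penalized
  `smooth.spline` fit (fixed `spar`, or `"gcv"` for generalized
  cross-validation) is available for noisy per-sample data. Group-mean
  profiles, the intended default input, are smooth enough to
  interpolate.
* **Integration and tabulation.** The fitted function, clipped at zero,
  is accumulated by the trapezoid rule on a 0.25 µm grid. For the smooth
  profiles in scope the trapezoid error is far below every tolerance
  used; the same tabulation doubles as the curve's monotone
  representation, so the inversion is exact for the represented curve.
* **Domain handling.** When samples start above eccentricity 0, the
  innermost value is extended to 0 as a constant. `E_max` beyond the
  fitted domain is a range error, not an extrapolation.
* **Inversion and ties.** The cumulative values are non-decreasing by
  construction (non-negative integrand). The inversion returns the
  *smallest* crossing eccentricity; on a plateau (a stretch of zero
  thickness) the horizontal distance would otherwise be ill-defined.
* **Unreachable targets.** If `Cum_C(E)` exceeds the preterm curve's
  total, the cell is reported as unreachable rather than clipped;
  `retardation_profile()` records the failure per eccentricity.

Group summaries average retardation over all (layer × eccentricity)
cells in a 300–900 µm window — the convention that reproduces the
published per-group means (46/145/291 µm) from the packaged reference
cells exactly — reporting the rounded integer alongside the raw mean.

## The FDA index and lateral scaling

The foveal developmental arrest index,
`FDA = t_HFL+ONL / (t_IRL + t_OPL)` at FC, is high in mature foveas
(controls ≈ 13) and low when inner tissue persists. The classification
threshold defaults to 5 with an inclusive ("immature if ≤ 5")
convention, taken from the clean separation of published group means
(immature groups at 5 and 2; mature at 13 and 21); the boundary value is
deliberately classed immature because the immature group means sit *at*
the threshold.

Eccentricities from eyes of different axial length are rescaled with a
reduced-eye relation, factor `(AL − 1.82)/(AL_ref − 1.82)`; the 1.82 mm
constant is the reduced eye's nodal-point offset. The source analyses
cite an external scaling method without formulas, so the constant and
form here are the package's own documented choice, configurable via
`nodal_offset_mm`.

## The areal magnification model

Displacement spreads tissue over circles of growing radius, so available
lateral area scales with eccentricity squared. The model's pieces, each
a pure function:

| quantity | formula | default parameters |
|---|---|---|
| area ratio | `A = ((E − R)/E)²` | — |
| volume ratio | `V = T · A` | `T` = PG/C thickness ratio |
| pedicle diameter | `d = d₀ √A` | `d₀ = 6.3` µm, density 25 000 mm⁻² |
| sphere-equivalent diameter | `(ratio)^{1/3}` | caller picks the ratio |

The area formula is not written out in the source study; it was adopted
because it reproduces *every* one of the 36 published area cells from
the published integer retardations within ±0.015 (the slack is the
publication's own rounding of retardation before printing), and
`T × A` likewise reproduces all 36 volume cells
(`reproduce_reference_table()` recomputes both). The sphere-equivalent
operation takes the ratio to cube as an explicit argument because the
published 61%/48% diameters correspond to the cube root of the OPL
*areal* ratio at 300 µm, not of the tabulated volume ratio; rather than
guess intent the package lets the caller choose.

The normative displacement curve used by
`residual_displacement_pct()` is always a user-supplied table (e.g.
digitized from the literature), never bundled: it is external data, not
a model output.

## Synthetic cohorts and what they do (and do not) show

Raw per-subject thickness profiles are not published, so validation
rests on a generator with analytic ground truth.

**Control shape.** Every layer uses one functional family: thickness
runs from a central residual to a rim plateau through a normalized
logistic `s(e)` with `s(0) = 0`, `s(∞) = 1`. For inner layers
(residual < rim) this is a sigmoidal rise out of the pit; for HFL+ONL
(residual 170 µm > rim 60 µm) the complement — a smooth central hump
decreasing outward. Defaults anchor the FC stack to published control
values: summed IRL 8 µm, OPL 5 µm, HFL+ONL 170 µm (stack 183 µm against
a 185 ± 10 µm total-thickness anchor that also includes unmodelled
photoreceptor inner/outer segments; FDA = 170/13 ≈ 13.1 against 13 ± 3).

**Retardation warp.** Preterm profiles are generated by
`t_PG(e) = t_C(ψ(e))·ψ′(e)` — a change of variables that conserves mass
exactly, so `Cum_PG(e) = Cum_C(ψ(e))` and the ground truth is
`R(E) = E − ψ⁻¹(E)` in closed form (`linear_capped`) or by bracketed
root finding to 1e-10 µm (`saturating_exponential`, the default
`ψ(e) = e + r_max(1 − e^{−e/λ})`, chosen for its large central and
saturating peripheral blockage). The warp is phenomenological: the true
mechanism (traction vs migration) is unknown and not modelled.

**Which layers are warped.** Only the displacement layers GCL+IPL, INL
and OPL; HFL+ONL develops centripetally with the photoreceptors and is
generated un-warped. This matters: warping all layers by the same ψ
would multiply every FC thickness by ψ′(0) and leave the (scale-free)
FDA index unchanged, so synthetic preterms could never exhibit the
central IRL persistence that defines immaturity.

**Group defaults.** The warp's central compression is
`ψ′(0) = 1 + r_max/λ`, which multiplies inner-layer FC thickness, so
`(r_max, λ)` per group were set from the published FC anchors and
retardation ranges: PG1 (60, 600) → IRLt ≈ 8.8 µm, retardation
≈ 22–46 µm; PG2 (160, 85) → IRLt ≈ 23 µm, ≈ 137–160 µm; PG3 (330, 35) →
IRLt ≈ 83 µm, ≈ 250–330 µm. The resulting FDA values (11.9 / 4.5 / 1.3
vs control 13.1) separate cleanly at the threshold of 5.

**Noise.** Additive Gaussian thickness noise, truncated at zero —
segmentation jitter, the simplest adequate model. The default grid is
0–1200 µm at 25 µm, covering the 300–900 µm analysis window with margin
for spline edge effects. All randomness flows from the config seed
through per-(group, layer) sub-seeds, so output is byte-reproducible and
independent of generation order.

**What passing tests show.** Noise-free recovery of the analytic ground
truth (to < 0.5 µm across all 36 cells) demonstrates the estimator's
correctness. It does *not* bound its error on noisy data: the
retardation error at a cell is approximately the accumulated thickness
noise divided by the local layer thickness at the crossing point,
`sd ≈ σ·h·√(2E/h) / t(e*)` for noise sd σ on grid step h. With σ = 2 µm
and h = 25 µm this is a few µm for the thick GCL+IPL but 10–30 µm for
the thin INL and OPL near the centre — and no spline smoothing can
reduce it, because any linear smoother that preserves constants also
preserves the integral of the noise. Synthetic experiments across ten
seeds confirm this scaling. Real group-mean profiles, averaged over
subjects and segmented by hand, carry correlated errors this model does
not emulate; retardation values for thin layers should be read with
tens-of-µm uncertainty in mind.

**A-scans.** `synthesize_ascan()` builds banded reflectivity profiles
(error-function band edges over a softness scale; a zero-width band
degenerates to a Gaussian whose FWHM is `2σ√(2 ln 2)`), with stored true
boundaries. The OPL extractor places each border where reflectivity
crosses the midway level between the band peak and the flanking trough,
with sub-sample linear interpolation — whole-pixel quantization is
unacceptable for a layer 2–5 pixels thick. The midway rule is stated in
the source only for the INL-side border; the outer border applies the
same rule against the outer trough by symmetry. Peak plateaus resolve to
their midpoint; the search window is always caller-supplied (no anatomy
inference), and an optional absence of interior peak or flanking trough
is an error, not a guess. No 2-D B-scan simulation, speckle, registration
or flattening is attempted.

## Problem sizes

Tests run the generator on 49-point grids (0–1200 µm, 25 µm), tabulate
cumulative curves at 0.25 µm, and cross-check the inversion against a
brute-force 0.5 µm scanning oracle over 10 seeds × 3 groups × 3 layers ×
4 eccentricities; the whole suite completes in a few seconds.

## Known limitations

* The warp family couples central compression to asymptotic retardation;
  real foveas need not.
* Per-subject analysis is supported but the defaults follow the
  group-mean convention; no between-subject statistics are computed.
* The estimator's noise sensitivity for thin layers (above) is a
  property of the cumulative-inversion method itself, not of this
  implementation.
* Lateral scaling uses a single reduced-eye constant; individualized eye
  models are out of scope.
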
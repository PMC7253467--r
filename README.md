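# fovearrest

Morphometry of arrested foveal development from OCT retinal layer
profiles.

During normal foveal development the inner retinal layers (IRL: ganglion
cell + inner plexiform layer, GCL+IPL; inner nuclear layer, INL) and the
outer plexiform layer (OPL) are displaced centrifugally out of the foveal
centre (FC), excavating the foveal pit. In many adults born preterm this
displacement is arrested: inner-layer tissue persists at FC, the pit is
shallow, and the lateral space available to cone pedicles and inner-retinal
synaptic networks is reduced. `fovearrest` quantifies this arrest from
layer thickness-vs-eccentricity profiles (µm vs µm, temporal meridian)
measured on OCT B-scans, and models its structural consequences.

## The model

**Retardation of centrifugal displacement.** For each layer, thickness
profiles are fitted with a cubic spline and integrated from the foveal
centre outward into a cumulative thickness curve
Cum(E) = ∫₀ᴱ t(e) de. Because displacement conserves layer mass, the
horizontal offset between the preterm and control cumulative curves
measures how far displacement lags: the retardation at control
eccentricity E is

    R(E) = E − e*,   where e* = min { e : Cum_PG(e) = Cum_C(E) },

found by monotone inversion of the preterm curve.

**FDA index.** The foveal developmental arrest index at FC is
FDA = t(HFL+ONL) / (t(IRL) + t(OPL)); mature foveas score high (controls
≈ 13), inner-layer persistence drives it to ≤ 5.

**Areal magnification model.** Tissue that should reach eccentricity E but
stops at E − R occupies the smaller circle's area, so the available-area
ratio is A = ((E − R)/E)², the available-volume ratio is V = T·A with T
the PG/C thickness ratio, a cone pedicle at fixed density shrinks to
diameter d = d₀·√A (d₀ = 6.3 µm, density 25 000 mm⁻²), and a
sphere-equivalent structure diameter scales as the cube root of the
chosen ratio.

A seeded synthetic-cohort generator produces control foveal profiles and
"preterm" profiles through a mass-preserving retardation warp
ψ(e) = e + r_max(1 − exp(−e/λ)) with analytically known ground truth
R(E) = E − ψ⁻¹(E), so the whole pipeline is testable without raw scans.
A-scan reflectivity profiles with alternating hyper-/hyporeflective bands
can also be synthesized, and OPL thickness extracted from them by the
half-height ("midway point between peak and trough reflectivity")
criterion.

## Worked example

Pedicle minification at 300 µm eccentricity, from the packaged
group-level reference table (3 preterm groups PG1–PG3 of increasing
immaturity × 3 layers × 4 eccentricities):

```r
library(fovearrest)
opl <- subset(load_reference_table()$cells,
              layer == "OPL" & eccentricity_um == 300)
opl$retardation_um
#> [1]  27 156 199
a <- area_ratio(300, opl$retardation_um)
round(a, 4)
#> [1] 0.8281 0.2304 0.1133
round(pedicle_diameter(a), 1)
#> [1] 5.7 3.0 2.1
```

With OPL displacement retarded by 156 µm (PG2) and 199 µm (PG3), only
23% and 11% of the normal lateral area remains at 300 µm, and a normal
6.3 µm cone pedicle must shrink to 3.0 µm and 2.1 µm to keep its packing
density.

Parameter recovery on a synthetic cohort:

```r
cohort <- generate_cohort(cohort_config(seed = 1))
est <- cohort_retardation(cohort)
cmp <- merge(est, cohort$truth, by = c("group", "layer", "eccentricity_um"))
head(cmp[order(cmp$group, cmp$layer), c(1:4, 7)], 4)
#>   group   layer eccentricity_um retardation_um true_retardation_um
#> 1   PG1 GCL_IPL             300          22.23               22.23
#> 2   PG1 GCL_IPL             500          32.47               32.47
#> 3   PG1 GCL_IPL             700          40.03               40.03
#> 4   PG1 GCL_IPL             900          45.56               45.56
group_summary(est[est$group == "PG3", ])
#> <group_summary> PG3, 300-900 um: mean 310 um (range 250.11-330.38), n = 12
```

On noise-free profiles the estimator recovers the warp's analytic ground
truth to a fraction of a micrometre; `run_pipeline()` executes the whole
chain (simulate → retardation → FDA indices → magnification model) and
writes CSV tables plus a JSON report.

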
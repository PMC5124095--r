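# barCT

Micro-CT carbonate budgets from bioerosion accretion replicates (BARs).

## What it does

Coral reef frameworks persist through a balance between calcification and
bioerosion. A BAR — a block of cleaned dead coral skeleton on a PVC base —
records that balance: deployed on a reef for ~2 years and micro-CT scanned
before (59.51 µm voxel pitch) and after (64.23 µm), it carries the
signatures of four functional groups. `barCT` turns such a scan pair into
standardized carbonate-budget metrics:

* **accretion** — new carbonate outside the original block
  (cm³ cm⁻²),
* **macroboring** — internal void space > 100 µm within the remaining
  block (cm³ cm⁻²),
* **grazing** — external volume loss (cm³ cm⁻²),
* **microboring** — bulk density loss of the non-bored, non-grazed
  skeleton (g cm⁻²),

each divided by the initial surface area of the block (base excluded).

The voxel partition, with all masks registered on the pre-scan grid, is

```
accretion          = postMask \ preHull
original_remaining = postMask ∩ preHull
macroboring_void   = (postHull \ postMask) ∩ preHull
grazed             = preHull \ postHull
```

so that `|preHull| = |original| + |macroboring| + |grazed|` holds exactly.
Densitometry runs through per-session aragonite phantom calibrations
(`density = slope·attenuation + intercept`). Closed-chamber incubations
yield calcification by the alkalinity anomaly technique,
`G = −(ΔA_T/2)·m_sw/(SA·Δt)` in µmol CaCO₃ cm⁻² h⁻¹, oxygen fluxes in
µg O₂ cm⁻² min⁻¹, and the 11 h/13 h weighted daily mean. pH responses are
fitted with gaussian-identity or Gamma-log GLMs, sites compared by
Wilcoxon/Welch tests, and the pooled 24-h calcification model is solved
for the pH at which net calcification crosses zero, with a case-resampling
bootstrap CI. A seawater carbonate-system solver (Lueker 2000 constants,
total scale) connects alkalinity/DIC measurements to pH, pCO₂ and
Ω_aragonite.

A synthetic-data module (`barSimSpec`, `makeBarPair`, `makePhantomSet`,
`makeIncubationSet`, `makePhResponseTable`) generates every input the
pipeline consumes with exact voxel-counted ground truth, which is how the
package is tested end to end.

## Worked example

```r
library(barCT)

spec <- barSimSpec(blockDimsCm = c(1.2, 0.5, 0.3), seed = 42)
pair <- makeBarPair(spec)          # pre & post CTVolume + GroundTruth
cal  <- fitDensitometry(makePhantomSet(c(1.2, 1.6, 2.0, 2.4),
                                       slope = 0.01, intercept = 0.5,
                                       noiseSd = 1))
res <- quantifyBarPair(pair$pre, pair$post, preCal = cal, postCal = cal)
res$transform
#> RigidTransform: t = (2.512, -1.503, 1.000) voxels @ 59.51 um,
#>   rot = (0.802, -0.499, 0.605) deg, NCC = 0.9988
res$rates
#> FunctionalGroupRates (per initial surface area):
#>   accretion   0.00018398 cm^3/cm^2
#>   macroboring 0.00071646 cm^3/cm^2
#>   grazing     0.0013774 cm^3/cm^2
#>   microboring 0.01 g/cm^2
#>   SA initial 1.582 cm^2, final 1.680 cm^2; 662 days deployed
```

The simulated deployment imposed a pose change of (2.5, −1.5, 1) voxels
and (0.8, −0.5, 0.6)°; the transform recovers it to ~0.01 voxel. Each rate
is the voxel count of its label times the voxel volume, divided by the
initial surface area; multiply by 365/662 for annual rates (included in
`as.data.frame(res$rates)`).

```r
# chamber incubations: alkalinity anomaly + oxygen flux
calcificationRate(-20, 0.656, 30, 1.3333)   # 0.164 umol CaCO3 cm^-2 h^-1
oxygenFlux(1, 0.640, 30, 80)                # 0.2667 ug O2 cm^-2 min^-1

# where does pooled net calcification cross zero?
tab <- makePhResponseTable(-39, 5, n = 60, noiseSd = 0.3, seed = 7)
netZeroPh(tab$ph, tab$response)
#> CrossingEstimate: net calcification = 0 at pH 7.801
#>   (95% CI 7.787-7.815, n = 60, 1000 bootstrap draws)
```

A negative response below the crossing means net dissolution; the
simulated community switches sign near pH 7.8, and the estimator localizes
it to within a few hundredths of a unit at n = 60.

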
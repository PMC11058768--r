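---
title: "Methods: forage-based carrying capacity for an Arctic megaherbivore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forage-based carrying capacity for an Arctic megaherbivore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammothcap)
```

## The model

`mammothcap` estimates how many mammoth-sized grazers a landscape's annual
digestible forage production can support. The estimate is a chain of scalar
multiplications applied independently at every raster pixel — there is no
fitting, no spatial interaction, and no demography. That simplicity is the
point: every factor is a published, defensible constant, and the product is
a deliberately conservative bound rather than a calibrated prediction.

Per pixel, on the canonical Mg km⁻² scale,

$$\mathrm{AgDB} = \mathrm{AGBC} \times c \times
  \Big(\sum_{p} \mathrm{cover}_p\, d_p\, a_p\Big) \times r \times \nu$$

with

| symbol | meaning | default | units |
|---|---|---|---|
| AGBC | aboveground biomass carbon density | input raster | Mg C km⁻² |
| $c$ | carbon → total dry biomass | 2.03 | — |
| $\mathrm{cover}_p$ | fractional top cover of preferred PFT $p$ | input raster | fraction |
| $d_p$ | digestibility: forb 0.8, graminoid 0.5, deciduous shrub 0.6 | — | — |
| $a_p$ | preference adjustment: 0.5 for deciduous shrub, else 1 | — | — |
| $r$ | sustainable forage-utilization rate | 0.10 | fraction yr⁻¹ |
| $\nu$ | standing biomass → annually generated biomass (NPP) | 0.4 | — |

The preferred plant functional types are forbs, graminoids and deciduous
shrubs; evergreen shrubs, trees, mosses, lichens and algae are excluded
outright, which biases capacity downward. The cover-weighted digestibility
sum is the pixel's *downgrading factor*; at the default digestibilities it
lies in $[0, 0.8]$, with 0.8 attainable only under full forb cover. Run
reports log its min/mean/max so users can compare a real landscape's
distribution against published field ranges.

Density divides AgDB by one animal's annual need from the 2 % body-mass
daily dry-matter-intake rule. The body-mass range 3,900–5,200 kg (reference
mean 4,550 kg) gives 78–104 kg day⁻¹, i.e. 28.47–37.96 t yr⁻¹ over a fixed
365-day year (leap days ignored; the conventional 28–38 t figures are the
rounded presentation of these values). Downstream arithmetic always uses
the unrounded needs — rounding anywhere inside the cascade would compound
through the pipeline — and rounding to printed precision (half-up, via
`round_half_up()`) happens only in display helpers. Note the bound
convention: the heavier animal eats more, so the **high** body mass yields
the **lower** density bound; all tables label bounds by body mass to keep
this unambiguous.

Damuth's allometric law, $\log_{10} D = -0.75 \log_{10} W + 4.23$ ($W$ in
grams), provides an independent density estimate used as a cross-check
column in the comparison table, never as an input to the forage-based
estimate. Base-10 logarithms are required; the natural logarithm does not
reproduce the conventional 0.16–0.19 km⁻² range for this mass span.

## Uncertainty and sensitivity

The biomass input carries a per-pixel standard error. Confidence limits are
taken as $\mathrm{mean} \pm k\,\mathrm{SE}$ with $k = 1.96$ interpreting a
95 % prediction interval; $k$ is exposed as `pi_multiplier` because the
aggregation behind gridded "cumulative standard errors" in global biomass
products is not fully standardized. The lower limit is clipped at zero —
negative biomass is physically meaningless, the same logic by which cover
fractions are bounded to $[0, 1]$.

The sensitivity analysis is a deterministic 3 × 3 scenario grid — biomass
{LCL, mean, UCL} × forage rate {0.05, 0.10, 0.25} — not a Monte Carlo.
Published utilization spans roughly 7–87 % across megafaunal grazers, with
conservative cattle/bison practice at 25 % on grass and 12.5 % on wet
meadows; 0.05 and 0.25 bracket the 0.10 base rate within that envelope and
are configurable, not asserted. Because every step is scalar, grid cells
scale *exactly* linearly in the forage rate and NPP factor, and the grid is
monotone along both axes; the test suite asserts both properties, and the
zero-SE collapse (LCL = mean = UCL) is permitted and logged.

One ambiguity worth recording: whether the utilization rate applies to
digestible biomass or to total preferred-PFT biomass is mathematically
indistinguishable in a multiplicative chain, so the package does not
resolve it; stage tags (`total_biomass → digestible → foraged → annual`)
document one canonical order for readability only.

## The synthetic landscape

`generate_stack()` emulates the structure the analysis assumes of northern
Alaska, so the full pipeline can be exercised without real rasters:

* **Zones** are horizontal latitudinal bands (row 1 = north), four by
  default: coastal plain, foothills, mountains, boreal. Water pixels get
  the dedicated zone label 0, mirroring how water landscapes appear as
  zero-density strata in zonal summaries.
* **Biomass** is a per-band mean times spatially smoothed lognormal
  multiplicative noise (unit mean, `sdlog` 0.25, 3 × 3 box smoothing).
  Lognormal keeps pixels positive and right-skewed like real biomass maps;
  band means interpolate geometrically so the southernmost/northernmost
  ratio hits the configured value (default 2.0) in expectation.
* **Cover** profiles shift with latitude: deciduous shrub rises linearly
  from 0.10 (north) to 0.35 (south) while graminoids decline 0.35 → 0.20;
  forbs (0.05) and "other" (0.15) stay flat and evergreen shrub rises
  0.05 → 0.10. Small smoothed noise (sd 0.02) is added, then fractions are
  clipped to $[0,1]$ and rescaled wherever a pixel's sum would exceed 1.
* **Water** is the lowest `water_fraction` (default 0.05) of a smoothed
  random field — an exact pixel count, so the degenerate settings 0 and 1
  behave exactly. Water carries zero biomass and zero cover.
* **SE** is proportional to the mean (`se_fraction`, default 0.15).
* `mean_agbc_north = 1.5` Mg C ha⁻¹ is a calibration constant chosen once
  so that default synthetic densities land in a plausible 0–0.4 km⁻²
  envelope; it is a sanity band, not a claim of fidelity to any real
  landscape.

What the generator does **not** emulate: realistic spatial covariance
(the smoothing length is a free fixture parameter; nothing is known to
constrain it at 300 m), terrain, coastline geometry, per-PFT biomass
allocation (cover is used directly as a biomass share), and any real
coordinate system (the grid is abstract-georeferenced with an identity-like
transform in metres). Passing tests on synthetic stacks therefore validate
the *arithmetic and its invariants* — linearity, monotonicity, zero- and
nodata-propagation, zonal conservation, determinism — not agreement with
real-world numbers, which depend on the real input rasters.

## Numerical and I/O choices

* Internal areal unit is Mg km⁻² (1 g m⁻² = 1 Mg km⁻²; 1 Mg ha⁻¹ = 100
  Mg km⁻²); declared input units are converted once on entry.
* All cascade steps are scalar multiplications, so reorderings agree to
  double-precision rounding; the suite checks the vectorized path against
  an independent per-pixel scalar loop at 10⁻¹⁰.
* Nodata (`NA`) in any input layer propagates to nodata output; water is a
  real habitat with zero forage, encoded as 0, never as nodata.
* Rasters are exchanged as Esri ASCII grids (`.asc`) — a plain-text,
  GIS-standard single-band format — with values printed at `%.17g` so a
  write → read round trip is bit-exact for doubles; a JSON sidecar carries
  units, pixel size and the row-1-is-north convention, and zone names
  travel as a `label,name` CSV. Zone rasters are written and read as
  integers.
* Reports, CSVs and rasters use deterministic ordering (zones sorted by
  label) and fixed formatting; identical inputs reproduce every artifact
  byte for byte. Counts are kept real-valued internally and rendered to
  the nearest thousand (with a "~" prefix) only at presentation.

## Problem sizes

The test suite runs hand-oracle cases on 1- to 8-pixel grids, property
checks on 8 × 8 to 25 × 25 random stacks, and the full structural
acceptance battery on a 100 × 100 (900 km²) synthetic landscape, with
byte-level determinism checked at 50 × 50; the suite completes in a few
seconds on one CPU. These sizes were chosen as the smallest at which band
statistics are stable against the generator's noise.

## Known limitations

No seasonal NPP partitioning or winter forage availability; no demography
(body mass is an adult-male point estimate, deliberately conservative); no
predation, disease, fire, competition or landscape exclusion; no
belowground biomass; no probabilistic propagation of factor uncertainty
beyond the scenario grid. Totals computed on synthetic landscapes scale
with the synthetic area and are not comparable to any real region's totals.
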
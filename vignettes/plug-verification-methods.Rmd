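---
title: "Methods: gel and film verification of plug-based radiosurgery plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gel and film verification of plug-based radiosurgery plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plugdose)
```

## The problem

Gamma Knife radiosurgery can shield an organ at risk (OAR) by plugging a
subset of the unit's source channels with tungsten plugs, pulling the
isodose lines away from the OAR on one side of each shot. Plug-based dose
calculations are not part of routine acceptance testing, so a clinic that
uses plugging needs an independent, preferably volumetric, check that the
planned asymmetric falloff is actually delivered. `plugdose` implements
that check as a reproducible pipeline: a reference ("calculated") dose
grid is compared against a volumetric polymer-gel measurement read out by
multi-echo MRI, and against a planar radiochromic-film measurement, using
the gamma index, DVH-family statistics and profile/contour overlays.

Because no measurement data ship with the package, a synthetic phantom
module generates every input under seeded noise: the plan and its dose
grid, the virtual gel scan, the virtual film scan, and the calibration
fixtures. All pipeline stages downstream of the generator are the same
code a physicist would run on real data.

## The study configuration

The bundled study mirrors a three-shot plugged plan in a 16 cm spherical
phantom: shots with 18, 14 and 8 mm collimators at Leksell positions
(102, 84, 103), (101, 110, 101) and (76, 95.5, 106.5) mm, prescribed
8 Gy to the 50% isodose, so the plan maximum is 16 Gy. The calculated
grid is 2.5 mm isotropic, the gel readout is 0.5 × 0.5 mm in-plane with
2 mm slices, and all comparisons happen on a 1 mm isotropic grid over
the analysis subvolume X 70–115, Y 65–125, Z 90–114 mm (46 × 61 × 25 =
70 150 voxels), with voxel-center, inclusive-bound conventions
throughout.

## The dose model (synthetic stand-in)

The dose kernel is deliberately *not* a beam model. Each shot contributes
a product of three 1D logistic profiles `1 / (1 + exp((|u| - c/2) / (c/10)))`
with `c` the collimator size, giving a single maximum at the isocenter
and monotone falloff — the only properties the analysis relies on. Shots
are summed with their weights and the grid is rescaled so its maximum
equals prescription dose / prescription isodose. The raw (pre-rescale)
field is available through `evaluate_plan_dose()`, and the rescale factor
is stored in the generated grid's metadata so tests can compare resampled
grids against analytic values.

Plugs are azimuthal wedges about each shot's axis: a sector
`[start, end)` with transmission `t` multiplies the kernel by
`1 - (1 - t) m(phi) s(rho)`, where `m` is a raised-cosine-edged indicator
of the sector (10° edge width) and `s(rho) = rho² / (rho² + (2 mm)²)`
ramps the effect in radially so the field stays smooth on the shot axis.
The bundled plan blocks 45/21/46 of 201 channels per shot; lacking plug
positions, the wedge width is set to `360° × n/201` and oriented toward
the flanking OARs. This is a stand-in for the real plug geometry, chosen
to reproduce the qualitative one-sided isodose retraction, not the
delivered fluence.

Two modelling notes. First, plug monotonicity (a plug never increases
dose anywhere) holds for the raw kernel; after prescription rescaling it
cannot hold in general, because a plug that lowers the grid maximum
raises the rescale factor. Second, the logistic penumbra (width c/10) is
steeper than the 2.5 mm planning grid can resolve, so trilinear
interpolation of the planning grid carries errors of order 1 Gy in the
penumbra — exactly as sharp physical penumbrae do. The distance-to-
agreement component of the gamma index absorbs this (a sub-voxel shift
matches the dose), which is why the verification is phrased in gamma
terms rather than pointwise dose difference.

## Virtual measurement model

`simulate_measured_dose()` composes, in order: resampling to the readout
geometry, multiplicative Gaussian dose noise (`sigma` as a fraction of
local dose), scaling by the gel sensitivity factor, and an isotropic
Gaussian blur. Defaults are the study conditions: 1.5% noise (the middle
of the 1–2% band a well-handled normoxic gel achieves), 0.5 mm blur
(monomer diffusion plus imaging point spread), and sensitivity 1/0.85 —
the gel over-responds so that the downstream comparison must recover the
0.85 dose scaling factor. Every stochastic step is bitwise reproducible
given its seed.

The virtual MR scan follows the mono-exponential CPMG model
`S(TE) = S0 exp(-TE·R2)` with the 8-echo protocol TE = 14, 28, …, 112 ms,
and `R2 = intercept + slope · dose` from the linear gel calibration.
Optional additive Gaussian magnitude noise is available; Rician noise is
deliberately not modelled because analysis voxels are high-SNR (the
lowest-signal echo of the highest-dose voxel still sits well above
magnitude-bias territory at the noise levels studied).

The virtual film scan inverts the film response per RGB channel
(dose → optical density → transmission counts `ref · 10^-OD`). The
synthetic response is defined as dose = quartic(OD) with positive
coefficients — red spanning the largest OD range per Gy, green and blue
0.6 and 0.4 of it — so the calibration stage's quartic fit is exactly
identifiable and the end-to-end film loop closes to numerical precision.
Pixels stay continuous in [1, 65535] until TIFF export quantizes them to
16 bits; scanner noise is additive in counts, and averaging five scans
reduces its variance five-fold.

## R2 mapping

`fit_r2_map()` fits `ln S = ln S0 - TE·R2` per voxel by weighted least
squares with weights `S²`, the variance-stabilized form whose first-order
behaviour matches the nonlinear fit. It is exact on noiseless decays over
the full observed range (1.65–83 s⁻¹; at R2 = 83 the last echo is ~9×10⁻⁵
of S0 and still fits exactly), deterministic, and fast enough for
10⁵-voxel maps in well under a second. `refine_r2_map()` adds per-voxel
Levenberg–Marquardt refinement for noisy data; at 1% signal noise the
refined estimates agree with an independent nonlinear solver to much
better than 0.5% per voxel, while the log-linear estimate alone differs
from it by up to ~1% (an O(sigma²) estimator difference).

The default signal floor is 0 — only non-positive samples are excluded.
A data-driven floor ("3× the background noise of the last echo",
implemented in `estimate_signal_floor()`) is the right choice on real
acquisitions with air background, but on synthetic phantoms there is no
background and a difference-based noise estimate on smooth noiseless data
is driven by the signal gradient, which would wrongly invalidate the
high-dose core. Voxels with fewer than two usable echoes are marked
invalid rather than raising an error, and invalidity propagates as
no-data through every downstream statistic.

## Calibrations and the dose scaling factor

The gel calibration is an ordinary least-squares line of vial mean R2 on
delivered dose (11 vials, 0–17 Gy; the bundled table lies on the line
through 1.65 s⁻¹ at 0 Gy and 83 s⁻¹ at 17 Gy). Residuals are kept so the
linearity diagnostic (residuals scattered randomly about zero) can be
tested; the suite runs a sign-runs test over 200 noisy replicates.
Conversion is the exact inverse `dose = (R2 - intercept)/slope` with
three out-of-range policies: clamp to the calibrated range, mark as
no-data, or extrapolate ("none"). The pipeline converts with "none"
before scaling, because with sensitivity 1/0.85 the raw gel dose
legitimately tops out near 18.8 Gy — above the calibrated 17 Gy — and
clamping there would bias the scaling factor; after scaling, doses are
back inside the range.

The dose scaling factor is the ratio of means, calculated over measured,
in a relatively uniform high-dose region — by default the interior of the
80% isodose of the calculated grid, its flattest plateau. When the two
grids differ in geometry both are first resampled onto a common 1 mm
isotropic grid (the comparison space): resampling the fine measured grid
onto the coarse 2.5 mm planning grid instead adds a ~1.5% trilinear bias
in the curved high-dose region, which alone would exceed the ±0.01
recovery tolerance. On the common grid the residual bias is ≈0.2–0.45%
and the factor is recovered to 0.850–0.858 across seeds at 1% noise.

The film calibration fits dose as a fourth-degree polynomial in OD per
channel (at least six strips, 0–10 Gy), reports R² per channel, selects
the working channel as the one with the largest OD response per Gy (red),
and flags — with a warning rather than an error — fitted curves that are
not monotone over the data span, which happens when a hard-saturating
response is forced through a quartic. Fitting dose-on-OD directly (rather
than OD-on-dose inverted) was chosen because inverting a quartic
analytically is ill-posed near saturation; both orientations of the data
are available to the user since the strip table carries raw OD.

## Grid operations and comparison statistics

All resampling is trilinear at voxel centers with no extrapolation:
target voxels outside the source support become no-data, and no-data
source voxels poison any interpolated value that touches them. Trilinear
interpolation reproduces affine fields exactly, never leaves the source
range, and its error obeys the usual second-order bound `(h²/8)|D''|` per
axis — the property suite checks the bound against the analytic
generator's fine-sampled curvature.

The gamma index follows the standard dose-difference / distance-to-
agreement construction: for each evaluated voxel, the minimum over
reference positions within a search sphere of
`sqrt(|Δr|²/dta² + ΔD²/(tol·Dnorm/100)²)`. The candidate set is the
`interp_step` lattice (default dta/10) inside `search_radius` (default
3·dta), with the reference dose trilinearly interpolated; global
normalization to the calculated maximum is the default, local
normalization is a flag, and there is no low-dose cutoff unless asked
for — peripheral voxels are part of the result. The production path
(compiled, candidates sorted by distance, early termination once the
distance term alone exceeds the current minimum) is checked voxel-for-
voxel against `gamma_index_exhaustive()`, an independent plain-R
implementation that upsamples the reference separably and scans every
candidate; the two agree to ~10⁻¹⁴ on smooth random pairs. Minima found
on the search-sphere boundary are flagged as saturated, since the true
minimum may lie outside.

DVH curves are cumulative voxel-count histograms of the whole analysis
region (structure-based DVHs are out of scope). The DDDVH subtracts the
calculated differential histogram from the measured one and normalizes
by the total voxel count, so bins sum to zero exactly and a bin value of
0.01 means 1% of voxels shifted into that bin. The D4 diagram bins
voxels by calculated dose (5% of maximum per bin) and reports mean ± SD
of `100·(measured - calculated)/calculated`; the local denominator is
what makes low-dose bins show the characteristic >±10% spread under
absolute noise, and voxels with zero calculated dose are excluded and
counted. Isodose contours come from marching squares
(`grDevices::contourLines`) in mm coordinates.

## Problem sizes and determinism

The shipped study sizes were chosen so a complete verification run —
generation, MR simulation, R2 mapping, calibration, resampling and the
five-criteria gamma table on the 70 150-voxel comparison grid — finishes
in a few seconds on one core, and the full property suite plus the
oracle cross-checks in a few minutes. Every stochastic operation takes a
seed and reproduces bitwise; the pipeline derives stage seeds from one
master seed and records it in every report.

## What passing tests do and do not show

The synthetic study validates the *analysis machinery*: exactness on
closed forms, oracle equivalence of the gamma search, end-to-end identity
(a noiseless virtual measurement generated on the readout geometry, run
through the full chain, passes 100% at 0.5%/0.5 mm), parameter recovery
(the 0.85 sensitivity factor to ±0.01), and the qualitative tolerance-
ordering of the pass-rate table (monotone degradation toward the
strictest criteria, >90% at 3%/2 mm). It does not emulate registration
residuals, gel temperature/B1 nonuniformity, oxygen-inhibition edge
artifacts, scanner lateral response, or film orientation effects — the
effects that push real strict-criterion pass rates far below the clean
synthetic ones. Conclusions about a real gel or film measurement
therefore rest on this package's statistics being correct, not on the
synthetic pass rates being representative of a physical experiment.

## A worked example

```{r example, eval = FALSE}
library(plugdose)

config <- verification_config(seed = 1)   # bundled three-shot plugged study
report <- run_pipeline(config)
report
#> <comparison_report>
#>   dose scaling factor: 0.8548
#>   normalization: 16 Gy; 70150 voxels evaluated (0 no-data)
#>   gamma pass rates:
#>        3%/2 mm : 100.00%
#>        3%/1 mm : 100.00%
#>        2%/2 mm : 100.00%
#>        1%/1 mm :  99.94%
#>      0.5%/0.5 mm :  99.80%
```
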
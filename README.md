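# plugdose

Dosimetric verification of Gamma Knife treatment plans that use
**collimator plugging** — blocking selected source channels with tungsten
plugs to shield an organ at risk, which produces a one-sided dose
falloff that routine acceptance testing never checks. `plugdose` is for
medical physicists who want that check as a reproducible, testable
pipeline: a reference ("calculated") dose grid is compared against a
volumetric polymer-gel measurement read out by multi-echo MRI and a
planar radiochromic-film measurement, and a synthetic phantom module
generates every input under seeded noise, so the whole chain runs —
and is unit-tested — without scanner time.

## What it computes

**Gel route.** A CPMG echo series S(TE) = S0·exp(−TE·R2) is fitted per
voxel (variance-stabilized log-linear least squares, optional
Levenberg–Marquardt refinement) to an R2 map; the linear gel calibration
R2 = a + b·D converts it to dose; a dose scaling factor
mean(calculated)/mean(measured) over a uniform high-dose region absorbs
the gel's global sensitivity; both grids are trilinearly resampled to a
common 1 mm isotropic grid over the analysis subvolume.

**Film route.** Repeated flatbed scans are averaged, converted to optical
density OD = log10(reference/pixel) per RGB channel, and mapped to dose
through a per-channel fourth-degree polynomial calibration; the working
channel is the one with the largest OD response per Gy (red up to
10 Gy).

**Comparison.** The gamma index
γ(r_m) = min over r_c of sqrt(|r_c − r_m|²/DTA² + (D_c(r_c) − D_m(r_m))²/ΔD²)
with pass rate = % of voxels with γ ≤ 1, evaluated over tolerance
criteria from 3%/2 mm down to 0.5%/0.5 mm; cumulative DVH; the
differential-DVH difference (DDDVH, bins sum to zero exactly); the
dose-dependent dose-difference (D4) diagram (mean ± SD of percent dose
difference binned by calculated dose); line profiles; and
marching-squares isodose contours. A compiled gamma search is verified
voxel-for-voxel against a shipped exhaustive brute-force oracle. Dose
grids round-trip through DICOM RT Dose and a lossless array + JSON
sidecar format.

## A worked example

The bundled study is a three-shot plugged plan (18/14/8 mm collimators,
45/21/46 of 201 channels plugged) in a 16 cm spherical phantom,
prescribed 8 Gy to the 50% isodose — a 16 Gy maximum. The virtual gel
over-responds by 1/0.85 with 1.5% dose noise and 0.5 mm blur:

```r
library(plugdose)
report <- run_pipeline(verification_config(seed = 1))
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

Reading the output: the pipeline recovered the planted 0.85 gel
sensitivity factor from the data (0.8548, within 1%); the 70 150 voxels
are the 46 × 61 × 25 common-grid subvolume X 70–115, Y 65–125,
Z 90–114 mm around the three shots; and the pass-rate table shows the
expected pattern — essentially perfect agreement at clinical tolerances,
degrading as the criteria tighten toward 0.5%/0.5 mm. Isodose levels
convert as `relative_to_absolute(26, 16)` → 4.16 Gy, the line whose
retraction away from the OARs is the visible effect of plugging.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/plugdose.R run --seed 1 --out report-dir
```

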
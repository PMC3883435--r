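---
title: "Methods: from plate scan to fingerprint and concentration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plate scan to fingerprint and concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcode)
```

## The measurement model

A colorimetric sensing array places eight dye sensors (DC1–DC8) in the
wells of a 96-well plate, each sensor under one or more buffer conditions
and in two roles: a *control* well (sensor + buffer) and an *analyte* well
(sensor + buffer + analyte). Binding of the analyte perturbs each dye's
absorbance, which a flatbed scan records as a shift in the well's red,
green and blue channel values.

The package quantifies a scan in three steps:

1. **ROI totals.** Each well is reduced to the integer sums of its R, G
   and B channel values over a fixed region of interest. The default ROI
   is a disk of radius 10 px under the rule *pixel center within Euclidean
   distance ≤ r of the well center*, which contains exactly 317 pixels.
   Working with raw integer sums (rather than means) matches the scale the
   significance threshold is calibrated against.
2. **Differencing.** For every control/analyte pair and channel,
   `delta = control_total − analyte_total`, signed. Differencing against
   the paired control is the assay's own normalization; no background
   subtraction or white-balance correction is applied.
3. **Coding.** A channel contributes digit 1 when `|delta| >= 1000`
   (color-sum units). Digits are concatenated over all (sensor, condition,
   channel) slots into the identification code.

### Assumptions

* The plate grid is axis-aligned (flatbed scans made with a film area
  guide are); no rotation or perspective correction is attempted, and no
  automatic grid detection — geometry comes from the layout file.
* Illumination drift between a control and its paired analyte well is
  negligible; everything common to the pair cancels in the difference.
* Channel responses are linear in concentration over the assayed range,
  which is what makes a two-parameter standard curve appropriate.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `threshold` | 1000 | color-sum units | significance cutoff on `abs(delta)`; calibrated for 8-bit sums over the default ROI |
| ROI shape / size | disk, 10 px | pixels | must fit inside the well pitch; ROI area and threshold are coupled |
| `rescale_8bit` | off | — | integer-divides 16-bit channel values by 256 so the default threshold scale applies |
| peak window | 400–700 nm | nm | wavelength range searched for λ_max |
| `confidence` | 0.95 | — | coverage of the inverse-prediction interval |

The threshold and the ROI are coupled: doubling the ROI area roughly
doubles every `|delta|`, so a custom ROI calls for re-examining the
threshold. The digit comparison is **inclusive** (`|delta| >= T`), so a
difference exactly at the printed threshold counts as a change — this
keeps the threshold value itself meaningful, and the boundary behavior is
unit-tested so the convention is visible. The magnitude is thresholded,
not the signed value: a color change in either direction is a change.

## Digit ordering and library matching

Nothing in the chemistry fixes the order of the 48 digits, so the package
imposes one canonical order — sensors ascending (DC1 → DC8), conditions
ascending, channels R, G, B — and tags every code with an `ordering_id`
derived from the layout. Codes with different ordering ids are never
compared digit-by-digit; the tag turns a silent misalignment into an
error. With the default 8 × 2 layout the code has 8 × 2 × 3 = 48 digits.

Identification is nearest-neighbor Hamming distance against a library of
known codes. Hamming distance is the minimal faithful metric for
fixed-length binary fingerprints; all entries at the minimal distance are
returned, so ties are reported rather than silently broken.

## Standard curves and inverse prediction

Replicates (by default 3 plates × 3 assays = 9 differences per
concentration) are averaged first, and the curve is fitted to the
per-concentration means by unweighted ordinary least squares — the
protocol plots averages, so the fit matches what is plotted. `sd_delta`
and `n` are carried on each point but do not weight the default fit.
The Pearson correlation is reported signed; for a response that decreases
with concentration `r` is negative, and `|r|` is the quantity to compare
with a quoted correlation magnitude.

Inverse prediction uses the classical calibration estimator
`c_hat = (delta_obs − b) / m` with a first-order interval:

```
se(c_hat) = (sigma / |m|) * sqrt(1 + 1/n + (c_hat − mean(c))^2 / Sxx)
```

with `sigma` the residual standard error on the means and a Student-t
quantile on `n − 2` degrees of freedom. With two calibration points or a
perfect fit the residual scale is zero and the interval collapses onto
the point estimate. A slope whose magnitude falls below
`1e-9 × range(mean_delta)` is treated as flat: the concentration is not
identifiable and the inversion errors out rather than returning an
arbitrarily amplified estimate.

## UV-Vis analysis

λ_max is the grid argmax of absorbance, optionally inside a window — no
smoothing and no sub-grid (parabolic) refinement, because shifts are
conventionally reported at integer-nm resolution and the grid already is
1 nm in the default scenario. Ties break to the lowest wavelength,
deterministically. Peak shifts are signed with red (bathochromic) shifts
positive. Absorbance at an off-grid wavelength is linearly interpolated
between the bracketing grid points; extrapolation beyond the grid span is
refused. Replicate spectra are averaged point-wise and only on exactly
matching grids — silent regridding would blur the very peak positions the
analysis reports.

## What the synthetic generators emulate

The generators provide ground truth with the statistical structure the
analysis assumes:

* `render_plate()` paints control wells at a uniform baseline color and
  shifts each analyte well's responsive channels per pixel by
  `round(slope × c / pixel_count)`, then adds i.i.d. Gaussian pixel noise,
  rounds and clips to the channel range. The measured ROI difference
  therefore equals `slope × c` up to a rounding bound of half the ROI
  pixel count (±158.5 units for the default ROI) — a quantization the
  tests account for explicitly.
* `generate_difference_table()` draws replicate differences
  `delta = slope × c + Normal(0, sigma_delta)`; the default
  `sigma_delta = pixel_noise_sd × sqrt(2 × pixel_count)` is the standard
  deviation of a difference of two ROI sums of i.i.d. per-pixel noise.
* `generate_spectrum()` produces a single Gaussian absorbance band whose
  height and center move linearly with concentration, plus i.i.d. noise
  per grid point.

All randomness flows through an explicit seed argument; the global RNG
state is never touched, and equal seeds give bit-identical output.

### Default scenario constants and why

The ketamine spectrum scenario is anchored to the titration endpoints of
the DC1 band: center 516 nm and peak 1.05 AU at 0 mM, center 520 nm and
peak 0.66 AU at 90 mM, interpolated linearly (slopes +4/90 nm·mM⁻¹ and
−0.39/90 AU·mM⁻¹) because the absorbance response is linear over this
range to good approximation. The band sd of 30 nm is a typical visible
absorption bandwidth for an organic dye; it only needs to be broad enough
that the 515 nm read-out tracks the peak smoothly. The grid is 400–700 nm
at 1 nm. The UV-Vis concentration series is 5–90 mM and the plate-assay
series 10–100 mM, the ranges over which the assay was titrated.

The plate scenario's response slopes — DC1 green 50, DC2 blue 45, DC3
green 30 color-sum units per mM — are illustrative: no instrument slopes
are available to estimate them from. 50 units/mM for the headline DC1
green channel puts the 9-replicate, noise-sd-100 simulation in the same
signal-to-noise regime as a curve with correlation ≈ 0.99. The companion
slopes were then fixed so that no slot's noiseless response lands inside
the renderer's quantization band around the threshold at any assayed
concentration (e.g. a slope of 40 would put a response at exactly 1000 at
25 mM, which a delta quantized to multiples of 317 cannot represent
faithfully); with that constraint the rendered digits equal the ideal
noiseless digits and end-to-end identification is exact at zero noise.

### What they do not emulate

Real scans have spatially correlated noise, vignetting, white-balance and
ICC-profile effects, meniscus shadows and inter-well bleed; real
absorbance spectra have baselines, scattering and multiple overlapping
bands. None of these are modeled. Passing tests on synthetic data
therefore demonstrate that the *computational* pipeline is correct and
self-consistent — not that a particular scanner or chemistry will achieve
the same correlation coefficients.

## Numerical and degenerate-input conventions

* Pixel coordinates are 0-based, origin top-left, x rightward, y downward;
  well A1's center sits at the layout origin.
* 16-bit scans are analyzed at native depth unless `rescale_8bit`
  right-shifts them onto the 8-bit threshold scale (the choice is explicit
  because a threshold tuned on 8-bit sums is meaningless on 16-bit sums).
* Alpha channels are dropped with a warning; grayscale input is rejected.
* A layout whose analyte well lacks a control partner, a code compared
  against a library of a different length or ordering, a duplicated
  (sample, wavelength) pair, a calibration design with a single distinct
  concentration, and an ROI leaving the image all raise descriptive
  errors naming the offending well, slot or field.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at desk scale: 96-well layouts with 32 mapped wells (plus 8-well toy
layouts for the pixel-loop oracle), difference tables of 54 rows
(6 concentrations × 9 replicates), 48 spectra of 301 points
(8 concentrations × 6 replicates), and 300-iteration coverage checks for
the inverse-prediction interval. These sizes keep every oracle —
brute-force pixel summation, closed-form OLS, exhaustive grid scans —
cheap enough to run on every test invocation.

## Known limitations

* Single-channel calibration only; no multivariate calibration across
  slots, and no nonlinear (saturation/Hill) models — outside the linear
  range the standard curve is simply wrong, and the package does not
  detect that.
* λ_max is grid-limited; a true peak between grid points is reported at
  the nearest sampled wavelength.
* The master code library of real analyte fingerprints is not shipped;
  libraries are built by the user (or synthetically via
  `scenario_expected_code()`).
* Hamming matching weights every slot equally; a probabilistic matcher
  with per-slot reliabilities is out of scope.
```{r session, echo = FALSE}
sessionInfo()
```
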
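---
title: "Estimating corn leaf nitrogen content from canopy hyperspectral reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating corn leaf nitrogen content from canopy hyperspectral reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizeLNC)
```

## Problem

Leaf nitrogen content (LNC, % of dry mass) is the standard field diagnostic
for crop nitrogen status, but wet-chemistry assays are slow and destructive.
Canopy hyperspectral reflectance (350–2500 nm) carries nitrogen information
indirectly, mostly through chlorophyll absorption around 490 and 670 nm and
through the position and slope of the red edge (680–760 nm). `maizeLNC`
implements a complete estimation workflow:

1. **Preprocessing** — Savitzky–Golay smoothing, first-derivative transform,
   and masking of atmospheric water-vapor windows;
2. **Feature construction** — four families of candidate predictors:
   the masked reflectance bands, the first-derivative bands, 40
   continuum-removal/edge *position features*, and 34 published
   *vegetation indices*;
3. **Variable screening** — the successive projections algorithm (SPA)
   selects a small, minimally collinear subset within each family, using
   only calibration samples;
4. **Modeling** — partial least squares (PLS) and random forest (RF)
   regressions on each family's selection, then on the *integrated* pool of
   all selections, rescreened by SPA;
5. **Reporting** — R², RMSE, and NRMSE = RMSE/mean(observed) on calibration
   and validation sets, plus machine-readable selection and scatter tables.

## Preprocessing

**Savitzky–Golay smoothing** (`sg_smooth()`) uses a 17-point window and a
second-order polynomial — wide enough to suppress radiometric noise at 1 nm
sampling without eroding the red-edge inflection. Interior points use the
standard convolution weights; near the spectrum ends the same polynomial is
refit on the truncated one-sided window rather than padding, so no
fabricated reflectance enters the features.

**First derivative** (`first_derivative()`) is the forward difference
`(R(λ₂) − R(λ₁))/(λ₂ − λ₁)` reported at the interval midpoint, in nm⁻¹.
On a 1 nm grid this keeps derivative features aligned between samples and
makes the integral of the derivative recover reflectance differences
exactly (a property the test suite checks).

**Water-vapor masking** (`wavelength_mask()`) retains
[400, 1353] ∪ [1437, 1799] ∪ [1992, 2354] nm — 1680 bands on the 1 nm
grid — removing the 1350–1440 and 1800–1990 nm atmospheric absorption
windows and the noisy spectral extremes. Smoothing and differentiation are
performed *before* masking so interval borders do not create artificial
derivative spikes.

## Position features

For three absorption troughs (560–760, 920–1080, 1120–1280 nm) and six
reflectance shoulders (500–670, 780–970, 980–1200, 1200–1350, 1480–1720,
2000–2300 nm), the continuum is the straight chord joining the region
endpoints. With `Rc` the chord:

- **depth** = `1 − R/Rc` at the wavelength minimizing `R/Rc` (absorption),
  or `1 − Rc/R` at the maximizing wavelength (reflection);
- **area** = trapezoidal integral of `|Rc − R|` over the region (nm);
- **normalized depth** = depth/area (nm⁻¹), defined as 0 when both vanish.

These 9 + 18 = 27 values are joined by 13 edge parameters: maxima of the
derivative spectrum and their wavelengths over the blue (490–530 nm),
yellow (560–640 nm) and red (680–760 nm) edges; the green-peak maximum
(510–560 nm) and red-well minimum (650–690 nm) of reflectance; and the
integrals of the derivative over the three edge windows. Argmax ties
resolve deterministically to the smallest wavelength. The `SDr` integral
defaults to the red-edge window (consistent with `SDb`/`SDy`); a
`sdr_window = "red_well"` switch covers the alternative convention found in
the literature.

## Vegetation indices

`vi_registry()` holds 34 published narrowband and broadband indices in a
fixed serialization order, with broadband bands defined as unweighted means
over B [450, 520], G [520, 600], R [630, 690], red edge [705, 745] and NIR
[760, 900] nm (configurable via `broadband_config()`). Narrowband lookups
snap to the nearest grid point (≤ 2 nm away). Divisions use `safe_div()`:
a vanishing denominator yields `NA` plus a message, never an exception.

Three indices are printed with typographical errors in their source table:
as printed, GNDVI uses mismatched bands, red-edge NDVI is identically 1 and
MTCI identically −1. The registry's default `"corrected"` mode uses the
indices' original definitions; `mode = "paper_literal"` reproduces the
printed formulas exactly, and the two modes differ on precisely those three
rows (audited by the test suite).

## SPA screening

`spa_select()` implements the successive projections algorithm on
standardized columns. From each candidate start variable, the chain
repeatedly appends the column with the largest norm after orthogonal
projection onto the span of the selected set (rank-1 residual updates;
ties to the smallest column index). Every chain prefix is scored by the
closed-form leave-one-out RMSE of an ordinary least-squares fit.

Subset sizing follows the standard SPA parsimony rule (`size_rule =
"ftest"`): the smallest subset whose LOO RMSE is statistically
indistinguishable from the global minimum under an F test at α = 0.25.
With ~1680 candidate start variables and only 48 calibration samples,
strict RMSE minimization (`size_rule = "min"`, also available) rewards
chance fits of uninformative wavelengths; in repeated synthetic experiments
the F-test rule selects nitrogen-informative wavelengths (red edge /
chlorophyll wells) essentially always, while strict minimization does so
only about half the time. Screening uses calibration rows only; the test
suite asserts that permuting validation responses changes no selection.

## Models and metrics

PLS (`fit_pls()`, via `mixOmics`) chooses its component count by
leave-one-out cross-validation unless given; with all components on
full-rank data it reproduces ordinary least squares to 1e-8, a tested
identity. RF (`fit_rf()`, via `randomForest`) uses 500 trees,
`mtry = max(1, ⌊p/3⌋)`, a fixed seed for reproducibility, and records the
out-of-bag RMSE. Reported metrics are RMSE, NRMSE = RMSE/mean(observed),
and R² = 1 − SS_res/SS_tot (the coefficient of determination; the mean-only
predictor scores exactly 0).

## Synthetic data generator

`sim_config()`/`make_dataset()` provide a phenomenological canopy-spectrum
generator so the entire workflow is testable without field data. Defaults
mirror a typical field campaign: n = 72 samples, LNC drawn from a truncated
normal (mean 1.91, sd 0.59, range [0.82, 2.83] % dry mass), and a seeded
random 2:1 calibration/validation split (48/24).

The deterministic base curve encodes the qualitative nitrogen signals the
pipeline is supposed to find: low visible reflectance with a Gaussian green
peak at 550 nm; chlorophyll absorption wells at 490 and 670 nm whose depth
grows with LNC (`chl_gain`, default 0.035); a logistic red edge whose
inflection shifts by `red_edge_gain` (default 8) nm per unit LNC; an NIR
plateau at 0.45 + `nir_gain`·LNC; and SWIR water-absorption wells near 1450
and 1940 nm. I.i.d. Gaussian noise (`noise_sd`, default 0.005) is added and
the result clipped to [0, 1]. The generator is Gaussians-plus-logistic, not
radiative transfer: it exercises the pipeline's mechanics, not canopy
physics, and deliberately omits cultivar, fertilization and growth-stage
structure. A radiative-transfer backend could be swapped in through the
same `spectrum_set` interface.

## Numerical choices and problem sizes

- Integrals use the trapezoid rule on the native grid; the suite checks
  agreement with an adaptive-Simpson oracle within 1% on smooth features.
- All stochastic steps (LNC draws, noise, split, forests) are controlled by
  explicit seeds; identical configurations give byte-identical CSV output.
- Heavy repeated experiments in the tests (a 20-seed SPA wavelength-
  localization check) run on a 5 nm grid; the screening mechanics are
  resolution-independent, and single-run end-to-end checks use the full
  1 nm grid.

## Worked example

```{r example, eval = FALSE}
library(maizeLNC)
ds <- make_dataset(sim_config(seed = 20190601))
run <- run_lnc_pipeline(ds)
print(run)                       # selections + 20-row report table
write_reports(run, "results/run", ds$lnc)
```

The numbered scripts under `analysis/` run the same stages end to end and
write all tables under `results/`.

## Limitations

- Synthetic spectra are phenomenological; absolute performance numbers on
  them say nothing about field accuracy.
- The 34-index registry fixes one broadband convention; instrument-specific
  response functions are not modeled.
- SPA subset sizing is a heuristic; for very small calibration sets the
  F-test rule can under-select.
- PLS component choice by leave-one-out is O(n) model fits; for very large
  n a k-fold evaluator would be preferable.
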
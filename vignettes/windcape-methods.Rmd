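---
title: "Modelling windthrow density from CAPE: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling windthrow density from CAPE: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windcape)
```

## The scientific problem

Large windthrows — wind-driven forest gaps above 25,000 m² — are
carved by severe convective storms such as squall lines. Their spatial
density across the Amazon tracks the climatological convective
available potential energy (CAPE) of the local afternoon, when deep
convection peaks. `windcape` packages that empirical link: a
non-parametric density model fitted where windthrows have been mapped,
plus a delta-change scheme that translates projected CAPE increases
from Earth-system models (ESMs) into projected windthrow-density
increases. This vignette records the models, the tunable parameters,
the numerical choices, and what the synthetic test-bed does and does
not demonstrate.

## Parcel CAPE

CAPE is computed for a nondilute near-surface parcel lifted through an
environmental sounding, as a discrete sum over pressure levels:

$$\mathrm{CAPE} = \sum_i \mathrm{d}p \, H(b_i)\, b_i,
\qquad b_i = \frac{1}{\rho_i} - \frac{1}{\rho_{e,i}},$$

with $\rho_i$ the parcel density, $\rho_{e,i}$ the environmental
density, $H$ the Heaviside step function, and by default
$\mathrm{d}p = 10$ kPa over levels 100 kPa to 10 kPa. The sum of
positive specific-volume excesses times pressure thickness has units
J kg⁻¹ and is non-negative by construction.

The ascent itself is standard parcel theory with choices that the sum
formula leaves open; ours are:

* **Saturation**: Bolton's empirical vapour-pressure formula over
  liquid water. The `cape_config()` slot `saturation_formula` exists so
  alternatives can be added for sensitivity work.
* **Lifting condensation level**: Bolton's closed-form LCL
  temperature, then the dry adiabat gives the LCL pressure. Below the
  LCL the parcel conserves potential temperature and mixing ratio.
* **Moist ascent**: pseudo-adiabatic (condensate removed on
  formation, no entrainment — our reading of "nondilute"), integrated
  with fixed-step fourth-order Runge–Kutta at 500 Pa (`ascent_dp`).
  At that step the integration error is negligible against the 10 kPa
  level discretization; the test suite verifies agreement with an
  independent 10 Pa Euler integration that detects saturation
  incrementally rather than via the closed-form LCL.
* **Densities**: ideal gas with virtual temperature for the (possibly
  saturated) parcel; condensate loading ignored, consistent with
  pseudo-adiabatic removal. The environmental density uses temperature
  (and humidity when supplied) interpolated linearly in log-pressure;
  a dry environment is the default when no humidity profile exists.
* **Step function at zero**: a level with exactly zero buoyancy
  contributes nothing (strict $H$); the term is zero either way, the
  flag `zero_buoyancy_counts` only makes the convention explicit.
* **Levels below ground** (pressure above surface pressure) are
  excluded from the sum, not extrapolated; at least two usable levels
  are required.

Units are SI throughout (Pa, K, kg kg⁻¹). Reanalysis CAPE products
computed with different parcel definitions are *consumed* as fields,
never recomputed: the delta-change design below exists precisely
because the two CAPE definitions are not comparable in absolute terms.

## The windthrow-density look-up table

Per-event CAPE values (sampled from the climatology at event
locations, nearest cell center) are sorted and split into
`n_bins = 6` equal-count groups — equal counts avoid noisy tails that
equal-width bins would produce. Choices the "sorted and split" recipe
leaves open:

* **Edge placement**: interior edge $k$ is the midpoint between the
  last event of group $k$ and the first of group $k+1$, so membership
  of the fitted events is unambiguous.
* **Membership convention**: left-closed, right-open $[e_k, e_{k+1})$;
  the last bin is closed at $+\infty$ and the first edge is 0, under
  the assumption that density is similar for neighbouring CAPE values
  and does not keep increasing beyond the observed range.
* **Ties**: events with identical CAPE straddling a group boundary
  cannot be separated by any edge. They stay with their sorted-order
  group in the stored counts and a warning reports the discrepancy
  from edge-membership counts; fully collapsed edges are an error.
  With events sampled from a gridded field, ties are common (events
  sharing a cell share a CAPE value), so the warning is routine on
  synthetic data.
* **When counts don't divide**: group sizes differ by at most one,
  larger groups first.

Bin areas are the summed spherical cell areas of in-region cells whose
CAPE falls in the bin; density is count/area × 10⁴ (events per
10,000 km²). Bootstrap SDs resample the events with replacement
(default `n_boot = 10000`) and recount against *fixed* edges — the SDs
describe the per-bin density estimates of the original binning, which
matches treating them as per-bin error bars. The resampling is done
literally (chunked index resampling) rather than via the equivalent
multinomial draw, so the binomial closed form
$\sqrt{n p_k (1-p_k)}/\mathrm{area}_k \times 10^4$ remains an
independent check; the suite verifies agreement within 5%.

**Threshold.** The storm-favorable cutoff is operationalized as the
interior edge maximizing the contrast
(events above/area above) ÷ (events below/area below); it can also be
supplied as a constant (1023 J kg⁻¹ for replication-style runs).
`density_ratio()` reports that contrast at any threshold, splitting a
straddled finite bin linearly over its CAPE range; a threshold inside
the unbounded last bin is rejected rather than guessed.

## Delta-change projection

Per ESM, the fractional change
$\delta = (\mathrm{CAPE}_{\mathrm{fut}} -
\mathrm{CAPE}_{\mathrm{cur}})/\mathrm{CAPE}_{\mathrm{cur}}$ is computed
cell-wise on the model's own climatologies and applied to the
observational baseline as $(1+\delta)\times\mathrm{CAPE}_{\mathrm{base}}$.
Numerical guards: cells with current model CAPE below a configurable
floor (default 1 J kg⁻¹) are masked rather than divided; $\delta < -1$
is an error rather than a negative CAPE. An absolute-delta alternative
is deliberately not the default — relative scaling is more sensitive to
the model's historical baseline, and we expose the floor and masking
instead of asserting equivalence between the two conventions.

Favorable area sums cell areas with CAPE *strictly* above the
threshold. The expected event total under a field is
$\sum_{\mathrm{cells}} d(\mathrm{CAPE}) \cdot \mathrm{area}/10^4$ with
$d$ the fitted step function; the current total uses the model's own
prediction (not the observed count) so current and future totals are
computed identically, and only cells valid in both fields enter either
total. Ensemble summaries are means and sample (n−1) SDs across
models; percentages are carried at full precision and rounded to
integers only in the report table.

Period conventions (current ESM 1990–2015, future 2070–2099, baseline
1990–2019) and the 17:00–23:00 UTC afternoon window are configuration,
not hard-coded.

## Spherical-grid bookkeeping

Cell areas are exact spherical quadrilaterals
$R^2\,\Delta\lambda\,(\sin\varphi_2-\sin\varphi_1)$ with $R = 6371$ km;
the suite checks closure to $4\pi R^2$ within $10^{-6}$ relative.
Event-to-cell membership is half-open (a point on a shared edge
belongs to the east/north cell). Display-scale aggregation (e.g. a
2.5° 90th-percentile map of a 0.25° field) uses the linear-interpolation
percentile definition; grids anchor at the region's lower-left corner.
The region mask is any per-cell flag; the synthetic test-bed uses a
rectangle so no geographic boundary data is needed.

## The synthetic test-bed

The generators produce every input the pipeline needs, with known
ground truth:

* **Baseline field**: Gaussian-smoothed white noise (correlation
  length 2°, i.e. the smoothing kernel's SD), monotonically mapped to
  the observed afternoon-CAPE range 42–1549 J kg⁻¹. The map is
  piecewise affine with its knot at the area-weighted 62nd percentile,
  so 38% of the region's area lies above 1023 J kg⁻¹ — the observed
  storm-favorable fraction. Anchoring that split matters: with ~1/6 of
  simulated events below the intensity step, the first equal-count bin
  edge falls at the step, which is the regime the real analysis
  operates in. Smoothed noise was chosen over spectral methods for
  dependency-light reproducibility.
* **Events**: an inhomogeneous Poisson draw at cell level —
  count ~ Poisson(intensity(CAPE)·area/10⁴) per cell, uniform
  placement within the cell. Cell-level thinning (rather than exact
  continuous-space simulation) is adequate because the analysis itself
  is cell-resolved. The default intensity steps from 0.35 to 2.8
  events per 10,000 km² at 1023 J kg⁻¹: an eightfold contrast at the
  published threshold with rates near the observed density scale,
  yielding roughly 800 events on the default 0.25° grid.
* **ESM ensemble**: per model, a multiplicative log-normal baseline
  bias (SD 0.15, emulating non-comparable absolute CAPE), and a
  planted delta field = model-mean delta (drawn across models from
  Normal(0.26, 0.09), the reported ensemble CAPE increase) plus smooth
  spatial noise (SD 0.05). The planted truth is returned so recovery
  is measurable.

Everything is reproducible from integer seeds; pipeline runs offset
one master seed deterministically per stage.

**What passing tests do and do not show.** The test-bed demonstrates
internal correctness: equal-count bookkeeping, bootstrap calibration,
recovery of planted step intensities and planted deltas, and the
identity chain (zero delta ⇒ zero projected change). It does not
emulate real CAPE climatology features (orography, rivers, diurnal
artifacts), observation biases in event mapping (cloud cover, manual
identification), or any particular ESM's physics — so green tests
support the implementation, not the ecological conclusions one would
draw on real data.

## Problem sizes and runtime choices

The default synthetic scale mirrors the study's statistical shape
where that drives behaviour — ~800 events in 6 bins on a
100 × 80-cell (0.25°) field, 10 ESMs, 10,000 bootstrap replicates —
while unit tests use smaller grids (30 × 24 at 0.5°) where scale is
irrelevant. Replicated experiments (intensity recovery) use 25–100
replicates, enough that Monte-Carlo error is small against the 10%
bands they are checked to.

## Known limitations

* The pseudo-adiabat uses a constant latent heat and ignores ice
  processes; differences against more elaborate schemes are small
  compared with the 10 kPa level discretization but are not zero.
* `favorable_threshold()` only ever returns an interior bin edge; a
  change point between edges is found only to bin resolution.
* The density ratio of a fitted model is a slightly biased estimator
  of a planted intensity contrast when bin edges straddle the true
  step; the suite checks a 10% band on the mean over replicates.
* Fields must share a grid before being combined; only
  nearest-neighbor-style co-registration by construction is provided,
  not general regridding.
* The bootstrap quantifies sampling error of event counts only — not
  area uncertainty, location error, or detection incompleteness.
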
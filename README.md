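# windcape

Convective storms are the dominant cause of large, sudden tree-mortality
gaps — windthrows — in Amazon forests. Where the afternoon atmosphere
holds more convective available potential energy (CAPE), severe storms
and therefore windthrows are more frequent. `windcape` implements that
chain of reasoning as a tested pipeline for forest-disturbance
ecologists and climate-impact modellers: it computes parcel CAPE from
atmospheric soundings, fits an empirical windthrow-density model against
a CAPE climatology, and projects how windthrow frequency changes when
Earth-system models (ESMs) raise CAPE under a warming scenario.

## The model

**Parcel CAPE.** A near-surface parcel is lifted dry-adiabatically to
its lifting condensation level and pseudo-adiabatically above it
(nondilute: no entrainment; condensate removed on formation). On
discrete pressure levels `i` (default 100 kPa to 10 kPa in 10 kPa
steps),

    CAPE = Σᵢ dp · H(bᵢ) · bᵢ ,   bᵢ = 1/ρᵢ − 1/ρₑ,ᵢ

where `ρᵢ` is the lifted parcel's density, `ρₑ,ᵢ` the environmental
density at level `i`, and `H` the Heaviside step function — only
positively buoyant levels contribute, so CAPE ≥ 0 (units J kg⁻¹).

**Windthrow density.** Per-event CAPE values are sorted and split into
six equal-count bins; each bin's density is its event count divided by
the region area with CAPE in that bin (events per 10,000 km²). The outer
bin edges extend to 0 and +∞ (density assumed similar for neighbouring
CAPE values), giving a non-parametric step-function look-up table.
Per-bin uncertainty comes from 10,000 bootstrap resamples of the events
with bin edges held fixed. The interior edge that maximizes the density
contrast above/below defines the storm-favorable CAPE threshold.

**Delta-change projection.** Because reanalysis and ESM CAPE products
are not directly comparable, each ESM contributes only its fractional
change, `delta = (CAPE_future − CAPE_current)/CAPE_current`, applied
grid-wise to the observational baseline:
`CAPE_scaled_future = (1 + delta) × CAPE_baseline`. From current and
scaled-future fields the pipeline reports the percentage increase in
storm-favorable area (CAPE strictly above the threshold) and in the
expected windthrow total `Σ_cells density(CAPE) × area / 10⁴`, then
ensemble means and SDs across models.

## Worked example

Everything below runs on synthetic data generated by the package
itself — a correlated CAPE field spanning the observed 42–1549 J kg⁻¹
range with 38% of its area above 1023 J kg⁻¹, a Poisson point process
with an eightfold intensity step at 1023 J kg⁻¹, and a 10-member ESM
ensemble with planted fractional CAPE increases of mean 0.26, SD 0.09.

```r
library(windcape)

scenario <- synthetic_scenario(seed = 42)
field    <- make_cape_field(scenario)
events   <- simulate_windthrows(field, scenario$intensity_fn, seed = 43)
capes    <- sample_cape_at_points(field, events)
model    <- fit_density_model(capes, field)
model
#> <windthrow_density_model> 6 equal-count CAPE bins, 803 events
#>   [0, 1019.8):  134 events on    3748382 km2 ->   0.36 per 10^4 km2
#>   [1019.8, 1062.3):  134 events on     520351 km2 ->   2.58 per 10^4 km2
#>   [1062.3, 1108.8):  134 events on     439407 km2 ->   3.05 per 10^4 km2
#>   [1108.8, 1165.8):  134 events on     423491 km2 ->   3.16 per 10^4 km2
#>   [1165.8,   1255):  134 events on     521302 km2 ->   2.57 per 10^4 km2
#>   [  1255,    Inf):  133 events on     474477 km2 ->   2.80 per 10^4 km2
#>   storm-favorable threshold: 1020 J/kg

density_ratio(model)
#> [1] 7.866208
```

The fit recovers the planted structure: the storm-favorable threshold
lands at the first interior bin edge (1020 vs the planted step at
1023 J kg⁻¹), the low-CAPE bin has an order-of-magnitude lower density
than the rest, and windthrows are ~7.9 times more frequent above the
threshold than below it.

```r
ens <- make_esm_ensemble(field, scenario$esm_params, seed = 44)
res <- lapply(ens, function(e)
  project_model(e$model_name, e$current_cmip, e$future_cmip, field, model))
ensemble_summary(res)
#> <ensemble_summary> 10 models
#>   favorable-area increase: 94.0% (SD 8.8)
#>   windthrow-density increase: 68.1% (SD 6.2)
```

For this ensemble draw, raising baseline CAPE by the planted ~26%
roughly doubles the storm-favorable area and increases the expected
windthrow count by two-thirds; `projection_table()` renders the same
numbers as an integer-rounded per-model report.

A thin command-line wrapper over the same functions lives at
`inst/cli/windcape.R` (subcommands `simulate`, `cape`, `aggregate`,
`fit`, `bootstrap`, `project`, `densitymap`).

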
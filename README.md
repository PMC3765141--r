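# palmrisk

Spatially explicit identification of low-risk ("degraded") land for
sustainable oil palm expansion.

Oil palm certification schemes (RSPO, RSB, and the EU renewable-energy
directive) forbid new plantings on land carrying High Conservation Values —
protected areas and their buffers, habitats of endangered species, large
intact forest blocks, high carbon stocks, community lands — or land that is
biophysically unsuited to the crop. `palmrisk` turns those requirements into
a reproducible raster workflow for conservation planners and land-use
analysts:

1. **Rule tables.** Every indicator of the principle/criterion/indicator
   hierarchy (17 indicators under three principles: conservation values,
   human wellbeing and land rights, biophysical suitability) has a rule
   table mapping values to four ordinal risk classes of non-compliance,
   `LOW < MEDIUM < HIGH < VERY_HIGH` ("unsuitable"). Continuous tables
   (rainfall mm/yr, slope %, elevation m, erosion t/ha/yr, carbon t/ha,
   soil depth cm) are interval partitions; categorical tables (soil
   texture/drainage/chemistry, land rights, hydrology) are disjoint
   category sets. The built-in registry ships as a YAML config and is fully
   user-editable; a validator reports any gaps or overlaps.
2. **Composite layers.** Indicators that need geometry are built from masks
   and polygons: protected areas with a 1 km buffer zone, contiguous forest
   blocks larger than 20,000 ha with a 3 km buffer, species
   distribution/habitat/critical-site tiers.
3. **Maximum-risk overlay.** The indicator layers are superimposed per cell
   under Liebig's law of the minimum: the combined class is the *worst*
   class among the layers, `rim(x) = max_i layer_i(x)` on the 0–3 rank
   scale — land is only as usable as its most limiting factor. The result
   is the Risk Indicator Map (RIM).
4. **Zonal reporting.** The RIM is cross-tabulated against concession
   status (active/inactive) and provincial land-use-plan classes, and
   low-risk land is ranked by legal practicality: land for other use (APL)
   first, then conversion forest (HPK), production forest (HP/HPT), and
   protection forest last.

Because province-scale GIS inputs are proprietary, the package includes a
synthetic landscape generator (spatially autocorrelated fields thresholded
to target class proportions, plus random polygon layers) whose defaults
reproduce the published seven-layer marginal distribution for West
Kalimantan, so the entire pipeline is testable end to end.

## Worked example

```r
library(palmrisk)

reg <- load_rule_registry()                 # built-in thresholds
classify_value(reg$tables[["3.1.1"]], c(1600, 1100))
#> [1] "MEDIUM"    "VERY_HIGH"

# synthetic 60 x 60 province (1 ha cells) with the published marginals
bundle <- generate_scenario(scenario_spec(n_rows = 60, n_cols = 60, seed = 42))
rim <- combine_liebig(unname(bundle$layers))
tabulate_areas(rim, "RIM")
#>  label low_ha medium_ha high_ha very_high_ha total_ha low_pct medium_pct high_pct very_high_pct
#>    RIM     76       282     950         2292     3600       2          8       26            64

rank_expansion_options(rim, bundle$zones$land_use_plan, bundle$zones$concessions)
#>  priority                              zone low_risk_ha
#>         0 inactive concessions (first call)          19
#>         1                         other use          23
#>         2                 conversion forest          16
#>         3                 production forest          24
#>         4                 protection forest           9
```

A rainfall of 1600 mm/yr falls in the 1500–1750 medium band; 1100 mm/yr is
below the 1250 mm/yr floor and unsuitable. In the synthetic province only
2% of the area is low risk for every indicator at once — the overlay is an
intersection, so the combined low-risk share is far below any single
layer's — and the ranked table lists where that land sits: 19 ha already
inside inactive concessions (the first place to steer pending licenses) and
23 ha on land legally designated for other use.

The same stages run from the shell via the thin CLI:

```sh
Rscript inst/cli/palmrisk.R simulate --out demo --rows 60 --cols 60 --seed 42
Rscript inst/cli/palmrisk.R run --config demo/config.yaml
```

which writes class rasters (ESRI ASCII), `rim.asc`, cross-tab CSVs,
`recommendations.csv` and a markdown report under `demo/`.

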
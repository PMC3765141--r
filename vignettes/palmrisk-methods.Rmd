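---
title: "Methods: rule-based risk mapping for oil palm expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based risk mapping for oil palm expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmrisk)
```

## The model

`palmrisk` estimates, for every raster cell, the risk that converting that
cell to oil palm would violate sustainability-certification criteria
(RSPO/RSB/EU-RED aligned). The model has three parts.

**Ordinal classification.** Each indicator maps to one of four ordered risk
classes, `LOW(0) < MEDIUM(1) < HIGH(2) < VERY_HIGH(3)`; `VERY_HIGH` is
synonymous with "unsuitable". NODATA is outside the order and never
compares. Classification is purely rule-based — no weighting, no fuzzy
membership — because the underlying certification criteria are themselves
threshold rules, and because assigning defensible weights across, say,
carbon stocks and customary land rights is a policy question the method
deliberately leaves open.

**Maximum-risk overlay.** The combined class of a cell is the maximum rank
across its indicator layers (Liebig's law of the minimum): one very-high
indicator overrules any number of low ones. The overlay is commutative,
associative and idempotent, and implies two checkable consequences used in
the tests: the combined LOW region is the intersection of the per-layer
LOW regions (absent NODATA), and the combined LOW area can never exceed
the most limiting layer's LOW area.

**Zonal accounting.** Areas are cell counts times `cell_size² / 10⁴` ha,
which assumes a projected, equal-area CRS; the package checks grid
congruence (origin, cell size, dimensions, CRS) before any overlay and
refuses mismatches rather than reprojecting.

## Rule tables and the boundary convention

The built-in registry encodes 17 indicators. Continuous thresholds are
stored as explicit half-open intervals, closed at the *lower-risk* end: a
printed boundary value takes the less risky class (slope exactly 15% is
MEDIUM; rainfall exactly 1750 mm/yr is LOW; carbon exactly 80 t/ha is
HIGH; soil depth exactly 100 cm is LOW). The published threshold lists
print touching bands ("8–15", "15–30"), so some convention is required;
closing at the lower-risk end is applied uniformly, documented here, and
exercised by dedicated boundary tests. Two further encoding choices:

* The rainfall LOW band is two-sided (1750–5000 mm/yr) with VERY_HIGH as
  an explicit union (< 1250 and > 5000 mm/yr); unions of intervals are
  first-class in the rule format.
* The two erosion indicators (ecosystem-service erosion risk 1.2.2 and
  soil erosion risk 3.3.4) print marginally different band labels
  (15–60/60–180 vs 15–59/60–179 t/ha/yr) that denote the same partition
  under the half-open convention; they are encoded once and referenced
  twice.
* The community-provisioning indicator 2.1.1 prints numeric subsistence
  shares (<10%, 10–25%, 25–50%, >50%), so it is encoded as a continuous
  table on that share; its "cultural sites" qualifier is not representable
  as a scalar band and must be supplied as a separate categorical mask if
  used.
* Two tables are three-class partitions (1.1.1 has no HIGH band, 1.2.3 no
  MEDIUM band — the source reports no data for them); the validator
  accepts partitions that never emit a class.
* Categorical matching is exact, case-insensitive, on the stored category
  strings. Unknown categories fall to the table's default class with a
  warning: LOW for "no overlap"-style tables, NODATA for the soil
  attribute tables (an unrecognized soil class should not silently count
  as usable land). NaN or declared nodata is always NODATA, never LOW.

The registry serializes to YAML (`inst/extdata/default_rules.yaml`); the
validator reports gaps and overlaps exactly, by sweeping the elementary
pieces (breakpoints and the open intervals between them) and counting
matching rules on each.

## Composite layers

Three indicators need geometry rather than cell-wise lookup:

* **Protection (1.1.1):** protected cells are VERY_HIGH; cells within the
  buffer distance (default 1000 m) are MEDIUM; the rest LOW.
* **Forest blocks / ecosystems (1.1.3):** contiguous forest blocks larger
  than 20,000 ha (strict inequality; area measured *before* buffering)
  plus a 3 km ring are MEDIUM; two or more ecotone regions or endangered
  ecosystems HIGH; rare ecosystems VERY_HIGH; per-cell maximum of the
  tiers. Connectivity is 8-connected by default — diagonal forest
  continuity should not split a block — and configurable.
* **Species (1.1.2):** distribution overlap MEDIUM, habitat HIGH,
  breeding/nesting or other critical sites VERY_HIGH; per-cell maximum.

Buffer membership is by center-to-center Euclidean distance, the standard
raster distance-transform semantics: it is exactly testable (a 1 km buffer
on 1 km cells is the 4-neighbour cross; diagonal centers at √2 km are
excluded). Whether the original analysis used Euclidean or legal-boundary
offsets is not stated; Euclidean is the documented choice here. In the
composite builders NODATA in the primary mask propagates to the output;
geometry treats NODATA as absence.

Polygon rasterization marks a cell when its center lies inside a polygon
(even-odd rule, so holes behave correctly). Point-in-polygon testing uses
`mgcv::in.out`; connected-component labelling runs on an `igraph` lattice
graph; both are cross-checked in the tests against independent brute-force
implementations (ray casting; flood fill).

## Tabulation and the percentage denominators

Area tables report hectares and integer percentages rounded half-up.
Per-indicator rows and the combined-map row use each row's own total as
denominator — necessary because real input layers have differing coverage,
so row totals differ. The concession and land-use-plan cross-tabulation
rows of the published distribution, however, only reproduce with the
combined map's total mapped area as denominator; `cross_tabulate()`
therefore supports both (`percent_denominator = "zone"` or `"map"`), and
the pipeline report uses `"map"` for cross rows, matching the published
layout.

Two published inconsistencies are handled by reporting, not by special
cases: the combined map prints 0 ha MEDIUM although input layers contain
MEDIUM — possible under a pure per-cell maximum only if every MEDIUM cell
is overridden elsewhere — so the overlay is implemented pure and the
report flags the situation explicitly; and the low-risk-in-inactive-
concessions figure is printed inconsistently in the source (914,853 /
916,853 / 916,000 ha), so no quantity is pinned to it.

The default `nodata_policy` for the overlay is `"ignore"` (a cell is
NODATA only where *all* layers are NODATA), because the differing row
totals of the published distribution imply cells missing in some layers
still received a combined class; `"propagate"` is available for strict
analyses.

## The synthetic landscape generator

The generator emulates the *statistical* structure of province-scale
inputs, not any real geography: per-layer marginal class proportions
(defaults are the published seven-layer marginals, computed from the
printed hectare areas) and spatial autocorrelation. Fields are white noise
smoothed by an edge-normalized moving-average kernel — chosen over
spectral synthesis for exact determinism with no FFT edge conventions —
then standardized; thresholding at empirical quantiles (ties broken by
cell order) hits target proportions to within one cell while preserving
spatial pattern. For continuous indicators a monotone piecewise-uniform
transform produces raw value grids (mm/yr, t/ha, …) whose classification
recovers the same classes, so the classify stage can be tested against
real-unit inputs. Polygon layers (protected areas, concessions) are
star-shaped random polygons rescaled to exact shoelace areas.

Free parameters with no published counterpart were fixed once at
field-plausible values and are documented as such: correlation length
500 m (landscape mosaics vary at sub-kilometre scale); land-use-plan zone
shares 25/10/35/30% (other use / conversion / production / protection);
2–7 polygons per vector layer at 10²–10³ ha. The default working
resolution is 100 m (1 ha cells); the 30 m source resolution of real
inputs is supported but not default.

What passing synthetic tests does *not* show: real layers are mutually
correlated (forest, carbon and protection overlap strongly), have
irregular coverage, and carry registration error between sources. The
generator's layers are independent by construction — which is exactly what
the product-law check `P(combined LOW) = Π P(layer LOW)` exploits — so
synthetic results validate the machinery, not any provincial figure.

## Numerical choices

* Percent rounding: half-up to integers (`floor(x + 0.5)`), matching the
  published tables; banker's rounding would flip several printed values.
* Degenerate inputs: a constant field cannot be split into several classes
  (error); empty masks label zero regions; an empty layer list refuses to
  combine; inverted intervals are configuration errors naming the table.
* Determinism: every stochastic routine funnels through one seed;
  pipeline outputs (ASCII rasters, GeoJSON, CSV, YAML manifest, markdown
  report) contain no timestamps, so reruns are byte-identical — asserted
  file-by-file in the tests.
* Raster exchange uses the plain-text ESRI ASCII grid format with a `.crs`
  sidecar, and class rasters are rank-encoded 0–3; vector exchange is
  GeoJSON. Both are human-inspectable, which suits a method whose audience
  includes certification auditors.

## Problem sizes

The test-suite and acceptance computations use grids between 2×2 and
120×120 cells (10⁴ cells for the statistical checks: variance,
correlogram, proportion recovery, product law with a 99% binomial CI),
100+ random grids up to 60×60 per brute-force oracle comparison, and
40×40 to 100×100 end-to-end pipeline runs — sizes at which exhaustive
per-cell oracles are feasible while every algorithmic path (multi-region
labelling, buffer edge effects, NODATA handling) is exercised.

## Limitations

The method is a desk-scale screening tool: it flags where field HCV and
FPIC assessment is unavoidable; it cannot replace either. Indicator
weighting is deliberately out of scope, as are land-cover classification
from imagery, the upstream erosion and carbon modelling that produces two
of the input surfaces, greenhouse-gas life-cycle accounting, reprojection,
and proximity-to-infrastructure criteria.
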
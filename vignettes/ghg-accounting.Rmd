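---
title: "Land-cover GHG accounting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-cover GHG accounting: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghgscape)
```

## The accounting model

`ghgscape` computes an area-based greenhouse-gas balance for a landscape
divided into five land-cover categories — artificial surfaces, arable land,
forest, waterbodies and wetland — each split into subcategories that carry
their own empirical flux rates. The model is deliberately simple and
transparent: every flux is a product of an area (or an activity total) and
an empirical coefficient, so the whole pipeline is linear in its inputs.
That linearity is what makes it testable: doubling areas must double
fluxes, allocations must conserve totals, and dividing a flux by its area
must return the coefficient.

The assumptions to keep in mind:

- **Static coefficients.** Flux rates are long-term empirical means per
  subcategory. There is no climate, water-table or management response;
  inter-annual variability enters only through the coefficient
  uncertainties.
- **Areas are exact.** Only coefficient uncertainty is propagated
  (`coefficient_flux()` takes SD = area × coefficient SD). Mapping and
  classification error in the areas is acknowledged but not quantified.
- **Independence of uncertainty components.** Combined uncertainties are
  root-sum-of-squares (`combine_uncertainty()`). Where a published net
  uncertainty comes from Monte Carlo instead (the forest net), the pipeline
  carries it through as an override (`net_flux(..., sd_override = )`,
  `national_rollup(..., sink_sd_override = )`) rather than recomputing it.
- **Immediate harvest emission.** All harvested carbon converts to CO₂ in
  the harvest year; wood-product storage is out of scope.
- **External sector models.** Emissions from artificial surfaces and from
  livestock/field cultivation are inputs (municipal totals from energy- and
  agriculture-sector models); the package grids, aggregates and reports
  them but never computes them.

## Units, gases and conversions

The canonical internal mass unit is Gg of gas per year; Tg and Mg appear
only at I/O (`convert_unit()`). Gas metadata lives in `gas_species()`:
GWP₁₀₀ weights 1/28/265 for CO₂/CH₄/N₂O (the AR5 100-year set, fixed as the
default metric) and integer molar masses (44, 16, 44; elements C = 12,
N = 14), the convention of inventory practice. Both are overridable — e.g.
4-decimal IUPAC masses — but the defaults reproduce published inventory
arithmetic exactly. Elemental fluxes convert via molar-mass ratios; N₂O
carries two nitrogen atoms, hence the ×44/28 factor from N mass.

Sinks are negative fluxes internally; report writers render them negative,
matching inventory tables. Net = emission − |sequestration|, so callers may
pass a sink either as a magnitude or as a negative flux.

## Classification rules

- **Lake size classes.** Five classes with half-open boundaries [0.01, 0.1),
  [0.1, 1), [1, 10), [10, 100), [100, ∞) km². Published class limits are
  printed with overlapping endpoints; half-open intervals are the only
  self-consistent reading, so a 100 km² lake is class 5. Lakes under 1 ha
  are excluded from the accounting — a signal (`NA`), not an error, since
  sub-minimum lakes are a normal feature of registries.
- **Cropland.** Parcels on organic soil-map units (Gleyic Podzols, Umbric
  Gleysols, Fibric/Terric Histosols) split into annual/perennial organic
  classes; everything else is mineral regardless of crop. Unknown legend
  units are rejected by default (`unknown = "reject"`), with a lenient
  default-to-mineral mode for exploratory use.
- **Mires.** Four classes (productive forested mires, sedge fens, other
  open and sparsely treed fens, ombrotrophic bogs) assigned by a rule table
  over (productivity, site main class, fertility). The rule table is data,
  not code; the packaged default is a synthetic full-coverage table because
  the original classification key is not publicly printed. Attribute
  combinations missing from a table yield a counted "unclassified" signal.
- **Zones.** Cropland coefficients differ between the southern (regions
  1–16) and northern (17–19) zones; `zone_of_region()` makes the mapping
  configurable for synthetic landscapes. A zonal coefficient lookup falls
  back to the national row when no zonal row exists.

## Grids and resampling

Grids are plain integer/character matrices (row-major, north-west origin)
with a cell size in metres, default 250 m (0.0625 km² per cell); feature
registries are data frames. This keeps the accounting logic independent of
any geospatial I/O stack — rasters and vector layers can be ingested from
any source that can produce a matrix and a data frame.

Fine-resolution masks (e.g. 16 m forest-soil maps) are resampled to the
accounting grid by exact area-weighted overlap (`resample_fractions()`),
not nearest neighbour, because 250 is not a multiple of 16. The
implementation is separable (1-D overlap weight matrices on each axis);
tests compare it against a brute-force per-cell rectangle-intersection
oracle and assert exact area conservation.

Waterbody areas always come from the feature registries (lake polygons,
river polygons/lines), never from cell counts — cells are far too coarse
for shoreline-dominated features. Narrow (line-mapped) rivers contribute
length × 3.5 m assumed width.

## Flux engines

Each engine is a thin, linear map from areas/activities and a coefficient
table to per-gas fluxes:

- **Lakes.** Per lake: CO₂ = area × evasion rate of its size class; CH₄ =
  open-water area × (diffusion + ebullition) plus area × cover × species
  rate for each emergent macrophyte group. Whether macrophyte-covered area
  *substitutes for* or *adds to* the open-water CH₄ terms is genuinely
  ambiguous in the source material; substitution is the default (covered
  water is not open water) and `macrophyte = "additive"` is the switch.
- **Mires.** Soil CH₄ and N₂O emissions plus an ecosystem CO₂ balance per
  class. The CO₂ coefficient can be derived from the long-term apparent
  carbon accumulation rate with a constant leaching export
  (`derive_mire_co2_coefficient()`): the mass balance is
  accumulation = −CO₂-C − CH₄-C − leach-C, with switches exposing the
  convention (terms can be excluded) since the published derivation does
  not spell out its sign/term structure. CH₄ uptake is never netted against
  the CO₂ term.
- **Proxy allocation.** Municipal sector totals spread over cells
  proportionally to a non-negative proxy weight layer within each
  municipality's mask; conservation is exact by construction, all-zero
  masks fall back to uniform spreading, and biogenic-CO₂-flagged totals
  allocate as zero to avoid double counting.

## The packaged inventory transcription

`inst/extdata/` ships CSV transcriptions of a published national
accounting: the land-cover area table, the national flux table (with ±
uncertainty half-widths) and the regional table. Numbers are stored exactly
as printed; the printed component SDs are treated as abstract uncertainty
half-widths (their interval width is not stated) and only the combination
algebra is asserted. Known rounding quirks carried as-is: the arable
category total (22 537 km²) differs from its subcategory sum (22 421 km²)
and the waterbody total (33 896) from its sum (33 898), both artefacts of
independently rounded sources; one regional net (−1.754) differs by 0.001
from its printed emission + sink; and the wetland net intensity divides by
an ambiguous denominator (the mire area rather than the wetland category
area reproduces the printed value), so that one cell is left out of the
intensity checks.

Two packaged inputs are **synthetic stand-ins**, labelled so in their
filenames and headers: the per-region populations (reconstructed from
printed nets and per-capita values, so per-capita reproduction checks
arithmetic conventions only; the national per-capita uses the published
total population 5 503 664) and the coefficient table (derived as printed
national flux / printed area, because the published per-class coefficient
supplement is not available as text — each lake size class and mire class
therefore carries the national aggregate rate, and class-resolved behaviour
is exercised with synthetic coefficients instead).

## The synthetic landscape generator

`generate_landscape()` builds a complete input bundle with known ground
truth so every stage is testable offline: contiguous Voronoi regions, a
patchy category field thresholded by rank to hit target fractions exactly,
per-category subcategory mixtures, lake areas log-uniform over
[0.005, 300] km² (the lower bound sits below the 1 ha accounting minimum so
the exclusion path is exercised), river polygon/line records, municipal
sector totals, and a "true" coefficient table. Ground-truth fluxes are
computed inside the generator by direct per-cell / per-feature
multiplication — a deliberately naive accumulation loop, independent of the
engine code — and the end-to-end test demands exact agreement with
`run_pipeline()`.

Defaults mirror the study conditions: category fractions 3/7/69/11/10 %,
forest 83 % mineral / 17 % drained peat, organic soils a small share of
cropland, an 80 × 80 cell grid at 250 m with 4 regions (the last one
northern), 60 lakes. The generator emulates the *statistical* structure of
the real data sources, not their geography: there is no hydrology-aware
peat placement, no realistic road network behind the proxy layer, and no
spatial autocorrelation beyond patchiness — none of the engines depend on
it. Passing synthetic tests therefore demonstrates correctness of the
accounting arithmetic and plumbing, not fidelity of any national map.

All draws come from one seeded stream; the generator saves and restores the
caller's RNG state, and a seed reproduces the landscape byte-identically.

`calibrate_to_areas()` rescales per-subcategory areas multiplicatively to
match a target area table (registries rescaled consistently; lake size
classes kept fixed under scaling so class membership does not churn), which
lets a synthetic landscape reproduce the published national areas exactly
while every flux stays linear in the scaling.

## Numerical choices and degenerate inputs

- Quadrature is the only uncertainty combiner; negative SDs are rejected
  everywhere at construction.
- Zero areas give zero fluxes with zero SDs; zero/missing area or
  population make intensity and per-capita `NA` (missing), never infinite.
- Negative nets, intensities and per-capita values are legal outputs
  (sink regions) and are never clamped.
- Report output rounds to table precision only at I/O; all internal
  arithmetic is double precision.
- Problem sizes in the tests and analysis scripts (80 × 80 to 200 × 200
  grids, tens of lakes, 10 × 10 resampling oracle) were chosen as the
  smallest instances that exercise every class and code path; all results
  quoted in the README are produced by the scripts at these sizes.

## Known limitations

- No land-cover change over time, no scenario machinery, no GWP20/GTP
  metrics (AR5 GWP₁₀₀ fixed as default).
- Fractional per-cell covers are supported by the resampler, but the
  accounting assigns whole cells to single subcategories; mixed cells at
  250 m are a recognised approximation.
- The packaged coefficient table reproduces national totals by
  construction; it cannot validate per-class rates. Any analysis needing
  real class-resolved coefficients must supply its own table
  (`read_coefficient_table()`).
- Spatial proxy quality is not assessed; allocation is only as good as the
  proxy layer.
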
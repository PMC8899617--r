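---
title: "Methods: persistent precipitation refugia from gridded time slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: persistent precipitation refugia from gridded time slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugia)
```

## The model and its assumptions

The package operationalizes a classic refugium concept for low-latitude
hunter-gatherers: habitability is governed by water availability, summarized
as mean annual precipitation (BIO12, mm yr⁻¹), and a refugium is a place
that stays habitable through an entire period of climatic stress. Concretely,
for a precipitation cube $P(x,t)$ on a regular lat/lon grid with uniform
1-kyr age slices, and a habitability envelope $[L, U]$,

$$\mathrm{refugium}(x) \;=\; \bigwedge_t \; L \le P(x,t) \le U .$$

Three assumptions are worth making explicit. First, precipitation alone
stands in for habitability: temperature, groundwater and surface-water
buffering are ignored, so persistently dry-but-watered landscapes (e.g.
spring-fed "hydro-refugia") will be misclassified. Second, the envelope is
transferred from recent ethnographic foragers to Pleistocene populations —
it bounds where recorded fully mobile groups live, not where people *could*
live. Third, the AND over slices is strict: one excursion in one millennium
removes a cell, which is conservative and makes results sensitive to the
temporal resolution of the input model.

The two standard envelopes are symmetric-tail intervals covering 68%
("narrow") and 95% ("broad") of the forager precipitation niche. Because the
intervals are nested, narrow refugia are a subset of broad refugia on every
input — an invariant the test suite asserts rather than assumes.

## Deriving the envelope

`derive_envelope()` supports two constructions:

- **percentile** (default): empirical quantiles at $(1-c)/2$ and
  $1-(1-c)/2$ with linear interpolation between order statistics
  (`stats::quantile` type 7). Documented so the bounds are reproducible
  bit-for-bit. This is the default because published forager envelopes are
  asymmetric about the median in a way consistent with empirical quantiles
  of a right-skewed niche distribution.
- **lognormal**: $\exp(\mu \pm z_c\,\sigma)$ of the log values. Offered
  because precipitation niches are often modelled as lognormal; it requires
  strictly positive values and is recorded in the output metadata.

The exact recipe behind the classic printed bounds (248–1403 and
127–3286 mm yr⁻¹) is not recoverable without the source table, so both
constructions are exposed and the method travels with the `threshold_pair`.
An all-equal input yields a zero-width envelope, returned with a warning and
flagged rather than rejected: downstream it simply selects cells pinned to
one value. The habitability test uses the **closed** interval $[L, U]$, so a
cell exactly at a bound counts as habitable.

## Grid conventions and numerical choices

- **Land**: a cell is analysable only if non-missing in *every* slice of
  every cube used; cells with gaps are excluded from all statistics.
- **Registration**: cell centres, rows north→south. Point-in-cell lookup
  uses half-open bounds $[\text{south}, \text{north}) \times
  [\text{west}, \text{east})$, so a site on a shared edge belongs to
  exactly one cell; the implementation guards the edge arithmetic with a
  $10^{-9}$ float tolerance.
- **Areas**: spherical cell area $R^2 \Delta\lambda (\sin\varphi_N -
  \sin\varphi_S)$ with $R = 6371$ km. "Percent of area" outputs are
  area-weighted by default, but the raw cell-count fraction is always
  emitted alongside, because sources rarely say which convention they use
  and the two differ on grids spanning many latitudes.
- **Temporal s.d.**: sample divisor ($n-1$) by default, configurable and
  recorded; CV = sd/mean, set to missing where the mean is zero.
- **Histograms**: left-closed right-open bins with a closed last bin;
  values outside the edges go to open overflow bins so shares always total
  100%.
- **Recurrence classes**: mean recurrence $r = \text{span}/n$ for $n$
  transitions over the axis span (120 kyr by default — the span, not the
  slice count). Boundaries belong to the slower class ($r = 20$ kyr is
  "60–20 kyr"), and an explicit ">60 kyr" class holds the realizable
  single-change case ($r = 120$) that narrative class schemes omit.
- **Ties**: the modal biome resolves ties to the smallest code; a 50/50
  open/forest cell is classed `changing_open`. Both are arbitrary but fixed
  and documented, so outputs are deterministic.
- **Ecotone windows**: the 3×3 neighbourhood *includes* the centre cell;
  off-grid and sea neighbours are simply dropped (no wrap-around), so
  coastal windows shrink. Ecotone outputs are invariant under swapping the
  open/forest labels.
- **Nodata**: −9999 in float rasters, 255 in byte masks.
- **File formats**: cubes are stored as a commented-header plus wide-CSV
  text format and single-band layers as ESRI ASCII grids — both plain-text,
  georeferenced, GIS-readable, and round-trip bit-identically.
- **Connected components** (largest contiguous refugial areas) are labelled
  via an adjacency graph under rook (4) or queen (8) connectivity,
  relabelled in decreasing size order.

## Occupation records

Ages are ka BP, so `age_min` is the younger bound. Age intervals are treated
as **closed**, and a continuity gap is an uncovered open interval between
them, with duration the difference of its bounds: dated ranges 92–70 and
69–58 ka leave exactly one 1-kyr gap (70–69 ka). By default
`continuity_gaps()` sweeps the span of the records themselves, so gaps are
breaks *between* occupations; pass an explicit window to audit coverage of
the whole Late Pleistocene. The window filter on central ages (10–130 ka) is
inclusive at both edges. Records with a missing central age are
mid-pointed; rows violating `age_min ≤ age_central ≤ age_max` are dropped
with row-level warnings rather than failing the load. Zone assignment uses
precedence narrow > broad > beyond, and the region split is an input column,
not inferred from coordinates.

## The synthetic study system

`synth_params()` fixes the study conditions the test-suite and the
acceptance script run under: a 24 × 36 cell grid at 0.5° with a one-cell sea
border, 121 slices (130–10 ka), a 100–1600 mm west–east baseline gradient,
sinusoidal forcing of amplitude 80 mm and period 21 kyr (qualitatively
mimicking precessional variability) with a smoothly varying spatial phase,
Gaussian noise with s.d. 30 mm, nine precipitation-binned biome classes
(200-mm bins, open/forest split at 1000 mm) with 5% adjacent-code jitter,
and a planted central block of refugial cells. The amplitude and noise were
chosen so that a typical cell's trajectory is dominated by its spatial
baseline but crosses envelope and biome edges at realistic rates; the
164-record site catalogue with 77% of records inside the planted refugia
mirrors the scale of a regional Late Pleistocene occupation record.

The generator is exact about its ground truth: planted cells are clipped
into the envelope in every slice, and any other land cell whose trajectory
happens to stay inside is forced out in one seeded slice. The planted set is
therefore *identical* to the persistently habitable set, which is what makes
parameter-recovery tests sharp (zero-noise recovery must be exact, and
noisy recovery is held to a Jaccard overlap of at least 0.95 across 20
seeds). Everything is deterministic given a seed (Mersenne-Twister with
inversion sampling, set explicitly).

What the generator does **not** emulate: realistic spatial autocorrelation
beyond a smooth gradient, glacial–interglacial asymmetry, teleconnections,
biome assignment from anything but local precipitation, or taphonomic and
research-intensity biases in site catalogues. Passing tests therefore show
the *pipeline* is correct under the model's assumptions, not that the model
is adequate for any particular real climate reconstruction.

## Problem sizes

The default test and acceptance runs use 24 × 36 × 121 (full axis) and
12 × 16 × 25 (coarsened 5-kyr axis) cubes, 100-replicate oracle-equivalence
sweeps on grids up to 7 × 7, and 164–1000-record site catalogues. These
sizes make every oracle comparison exhaustive (loops over all cells,
slices and windows) while keeping a full run of the suite in tens of
seconds.

## Known limitations

- Tier-scale reproduction of continental results requires the external
  climate/biome cubes and ethnographic table; the package validates the
  method on its synthetic system and exposes readers/derivers for the real
  inputs.
- The open/forest dichotomy collapses very different forest resource
  structures; the shipped 16-class lookup (`inst/extdata/biome_legend_16.csv`)
  is a reasonable default and fully overridable.
- No reprojection or resampling: inputs must already be co-registered.
- Persistence is binary; "nearly persistent" cells (habitable in, say, 120
  of 121 slices) are invisible unless examined via `ecotone_persistence`-style
  fraction layers, which the per-slice `slice_habitability()` output makes
  easy to build.
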
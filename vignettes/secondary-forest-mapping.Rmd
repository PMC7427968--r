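---
title: "Mapping secondary-forest age from annual land-cover series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping secondary-forest age from annual land-cover series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrowmap)
```

## The problem and the model

Annual land-use/land-cover products such as the MapBiomas collections
classify every 30-m pixel of a territory into a legend of integer codes,
year after year. A single year's map cannot distinguish old-growth forest
from regrowth; the distinction lives in the *history* of each pixel. This
package encodes that history with four coupled per-pixel recurrences.

A pixel becomes secondary forest (an **increment**) in year $y$ when three
conditions hold simultaneously:

1. it is forest in $y$ (forest-formation class only — mangrove and forest
   plantation are excluded from the forest class);
2. it carried an **anthropic** cover in $y-1$: forest plantation, pasture,
   agriculture, mosaic of agriculture and pasture, urban infrastructure, or
   mining;
3. it lies outside the static **maximum water extent**.

Condition 2 is the heart of the definition: regrowth on natural non-forest
cover (savanna, grassland, wetland vegetation) is *never* counted, because
without an anthropic intermediate there is no evidence that old-growth
forest was removed by human use. Condition 3 suppresses spurious
forest/non-forest flicker in seasonally flooded areas, where spectral
classification is least reliable.

The standing pool (**extent**) is then carried forward — a pixel stays in
the pool while it remains forest and leaves it the year it is cleared
(**loss**) — and **age** counts consecutive forest years since the most
recent qualifying increment. Clearing resets age to zero immediately; the
pixel only re-enters the pool on a fresh anthropic-to-forest transition,
with no cooldown period. With a record starting in year $s$, the first
detectable transition is $s \to s+1$, so increments and extents exist from
$s+1$, losses from $s+2$, and the age map of year $y$ is bounded by
$y - s$.

Two structural identities follow from the recurrences and are enforced as
tests rather than assumed: the pixel-count conservation law
$|E_y| = |E_{y-1}| - |L_y| + |I_y|$, and the equivalence
$E_y = 1 \iff G_y \ge 1$ between extent and positive age.

### The extent rule and its literal "sum" formulation

The extent recurrence can equally be phrased as bookkeeping on running
sums: keep a per-pixel accumulator of pool membership, add the year's
increment, threshold to binary, multiply by the year's forest mask (which
both removes cleared pixels and resets their accumulator). We implement the
Boolean form $E_y = (E_{y-1} \lor I_y) \land F_y$ and *test* that it is
identical to the literal accumulate/threshold/multiply procedure on random
mask series, rather than arguing the equivalence algebraically. The phrasing
ambiguity (what happens to accumulator values of exactly 1) dissolves under
this property: both readings that are consistent with the first-year base
case produce the same binary maps.

## Three independent implementations of one recurrence

Correctness of the raster engine is established by agreement of three code
paths written against the same definition but sharing no code:

- `run_timeline()` — vectorised whole-raster mask algebra;
- `pixel_oracle()` — a scalar scan of one pixel's class-code series;
- the ground-truth tracker inside `generate_stack()` — vectorised
  bookkeeping interleaved with the simulation itself.

The test suite and the acceptance script drive all three across random
synthetic landscapes (20 × 20 pixels × 40 years, 50 parameter draws, with
clearing, regrowth, natural regrowth, water fraction and nodata fraction all
varying) and require exact, pixel-for-pixel, year-for-year agreement. These
problem sizes make the full three-way comparison run in a few seconds while
still exercising every transition type thousands of times.

## What the simulator emulates — and what it does not

`generate_stack()` draws independent per-pixel Markov transitions:
forest → anthropic with probability `p_clear`, anthropic → forest with
`p_regrow`, natural → forest with `p_nat_regrow`, from initial cover
proportions on a 60 × 60 grid spanning 1985–2018 by default. Defaults
(`p_clear = 0.02`, `p_regrow = 0.05`, `p_nat_regrow = 0.02`,
`init_forest = 0.5`, `init_anthropic = 0.35`, `water_frac = 0.05`) give
slow net clearing with an actively regrowing anthropic pool — the regime the
algorithm is designed for. Natural regrowth is deliberately *on* by default
so that tests demonstrate the engine ignoring it.

The simulator is a correctness instrument, not a landscape model. It omits,
by design: spatial correlation of clearing (deforestation frontiers),
classification-noise flicker (single-year misclassifications that real
products smooth with temporal filters upstream), class-dependent transition
rates, and dynamic water. Passing its tests therefore shows that the
recurrences are implemented exactly — it says nothing about the accuracy of
any upstream classification, which bounds the accuracy of real products
built with this package.

## Carbon accounting

The uptake model is linear-then-flat: every secondary-forest pixel
accumulates carbon at the neotropical mean net rate
(`rate_mean = 3.05`, `rate_sd = 0.19` Mg C ha⁻¹ yr⁻¹) for its first
`age_cap_years = 20` years of succession, and stabilises afterwards — a
pixel older than the cap has null *current* uptake but retains the 20 years
it accumulated. At the default 0.09-ha pixel this gives
`r sprintf("%.3f", round_half_up(pixel_annual_uptake()[["mean"]], 3))` ±
`r sprintf("%.3f", round_half_up(pixel_annual_uptake()[["sd"]], 3))`
Mg C yr⁻¹ per pixel.

The rate uncertainty is treated as **fully correlated** across pixels: a
single shared rate error, so every standard-deviation output is
`mean × rate_sd / rate_mean`. Treating pixel errors as independent would
shrink aggregate uncertainty by the square root of the pixel count — an
unrealistic claim when all pixels share one literature-derived rate. The
correlated treatment makes the sd/mean ratio identical across zones, which
zonal tables exhibit, and makes uptake exactly additive over any partition
of pixels (a tested property).

Pixel area defaults to the constant 0.09 ha so that printed arithmetic is
exactly reproducible; latitude-dependent geodesic areas are out of scope.
Reported values are formatted with half-up rounding at the printed
precision (`round_half_up()`), with full precision retained internally; the
implementation nudges binary-representation ties (0.2745 stores just below
the decimal tie) to the away-from-zero side.

## Map-comparison statistics

Two binary maps are compared through per-cell cover percentages on square
blocks of the pixel grid (e.g. 333 px ≈ 10 km at 30 m; the tests use
smaller cells). Proportions are taken over *valid* pixels only and cells
with no valid pixels are dropped.

The bootstrap draws `ceiling(frac × N)` cells **with replacement** per
iteration (reading "raffled 10% of the cells with replacement" as a
resample of 10%-of-N cells), fits `prop_a = intercept + slope × prop_b` by
ordinary least squares, and records R², slope, intercept, and the residual
root-mean-square error. The regression direction — map under test on
reference map — is a documented choice; the published scatter does not pin
the axes, and swapping them changes slope and intercept but not the
qualitative comparison. A resample in which either column is constant
leaves the fit or its R² undefined and is redrawn (and counted). One seeded
generator feeds all iterations in order, so results are bit-reproducible
for a fixed `(seed, n_iter, frac)` and any parallelisation would have to
preserve the stream-per-iteration contract.

The Mann–Whitney test reports the U statistic for the first sample
(pairs won plus half the ties). Since the test itself is standard, the
p-value is delegated to `stats::wilcox.test()`: exact when both samples are
tie-free and `n_a × n_b ≤ 10000`, otherwise the normal approximation with
tie and continuity correction (exact enumeration under ties is not defined
in the reference implementation; this is the one deliberate narrowing of
the exactness rule). The brute-force pair-counting definition of U is kept
in the tests as an independent oracle. Interval-stratified tests bin cells
by the *reference* map's proportion with `[0,10], (10,20], …` boundaries on
the raw (unrounded) proportions, matching conventional integer labels
(0–10%, 11–20%, …) without committing to a rounding rule.

## Raster I/O and grid contracts

No reprojection or resampling is ever performed: every multi-raster
operation demands exact grid equality (dimensions, affine transform, CRS
identifier, nodata code), checked by `assert_aligned()`, which names the
first mismatching field. Nodata follows the most conservative defensible
contract: a pixel that is nodata in *any* input year (or in the water mask)
is nodata in every product, every year. Codes absent from the legend warn
once per code and behave as natural non-forest — the conservative reading,
since only listed anthropic covers can precede regrowth.

Products are written as single-band deflate-compressed GeoTIFFs: masks as
unsigned 8-bit, ages as unsigned 16-bit (33 fits in a byte, but 16 bits
cost little and remove a trap for longer records). Because age 0 and mask 0
are meaningful, the file nodata code must not alias data: 255 for masks and
65535 for ages whenever the grid's own code (conventionally 0 for class
maps) would collide. The codec itself — classic TIFF, strip-organised,
integer samples, pixel-scale/tiepoint georeferencing, geo-key directory,
GDAL nodata tag — is implemented in the package and cross-validated against
an independent TIFF codec in both directions (our writer read by the
independent reader; the independent writer read by ours). Tiled layouts,
floating-point samples, predictors and multi-band files are rejected with
explicit errors rather than mis-read.

One legend subtlety: forest plantation is *excluded* from the forest class
yet *included* among anthropic covers. The two roles are not contradictory
— standing plantation is not (secondary) forest, but a plantation replaced
by forest formation is a genuine regrowth event — so the legend permits the
overlap while still requiring the forest set to be disjoint from both
others.

## Known limitations

- Accuracy is bounded by the upstream classification; the package applies
  no temporal smoothing and will faithfully propagate single-year flicker
  into spurious loss/increment pairs (age resets included).
- The one-year look-back cannot see anthropic use that predates the record:
  forest present in the first year is indistinguishable from old-growth.
- The carbon model is age-capped linear with one biome-independent rate;
  climate- or region-dependent uptake curves are out of scope.
- The GeoTIFF codec reads the layouts this package and common
  deflate-compressed single-band products use; it is not a general-purpose
  TIFF library.
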
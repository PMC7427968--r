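# regrowmap

Annual secondary-forest **increment, extent, loss and age** mapping from a
time series of categorical land-cover rasters, with linear carbon-uptake
accounting and map-agreement validation statistics.

The package is aimed at landscape ecologists and remote-sensing analysts who
work with annual land-use/land-cover products such as the MapBiomas
collections for Brazil. Given one integer-coded class map per year on a
shared grid, it derives where and when *secondary* forest — forest regrowing
on land from which old-growth forest was completely removed by human use —
appears, persists, is cleared, and how old it is.

## The algorithm

Everything is a per-pixel recurrence over consecutive years. Writing
`F_y ∈ {0,1}` for the forest mask of year *y* (forest-formation class only;
mangrove and plantation excluded), `A_y` for the anthropic-cover mask
(plantation, pasture, agriculture, mosaic, urban, mining), and `W` for the
static maximum-water-extent mask:

- **Increment** (a pixel enters the secondary-forest pool):
  `I_y = F_y · A_{y−1} · (1 − W)` — regrowth is only counted after an
  *anthropic* cover; natural non-forest covers (savanna, grassland) never
  seed secondary forest, and wetland pixels are excluded to avoid false
  detections.
- **Extent** (the standing pool): `E_y = (E_{y−1} ∨ I_y) · F_y`, with
  `E_{s+1} = I_{s+1}` in the first transition year *s+1*.
- **Loss**: `L_y = E_{y−1} · (1 − F_y)`, from the second transition year on.
- **Age**: `G_y = (G_{y−1} + E_y) · F_y` — consecutive forest years since the
  most recent qualifying transition; clearing resets a pixel to zero, and
  age restarts at 1 only on a new anthropic→forest transition.

These rules satisfy an exact pixel-count conservation law,
`|E_y| = |E_{y−1}| − |L_y| + |I_y|`, which the test suite asserts on every
synthetic run.

Carbon accounting follows the linear neotropical model: each secondary-forest
pixel (0.09 ha at 30 m) takes up carbon at 3.05 ± 0.19 Mg C ha⁻¹ yr⁻¹ for its
first 20 years of succession and stabilises afterwards, so a pixel of age *a*
has accumulated `min(a, 20) × 3.05 × 0.09` Mg C.

Validation statistics compare two binary secondary-forest maps through
per-grid-cell cover percentages: a seeded bootstrap of least-squares fits
(R², slope, intercept, RMSE) and Mann–Whitney tests, overall and stratified
by the reference map's proportion interval.

Because no geospatial system libraries are required, the package ships its
own minimal single-band GeoTIFF reader/writer (integer samples, deflate
compression, pixel-scale/tiepoint georeferencing, GDAL nodata tag),
cross-validated in the tests against an independent TIFF codec.

## Worked example

Simulate a 60 × 60 landscape over 1985–2018, map it, and account its carbon:

```r
library(regrowmap)

sim  <- generate_stack(sim_params(seed = 42))
prod <- run_timeline(sim$stack, sim$legend, sim$water_max)
prod
#> <regrowth_products> 1985-2018: 33 increment/extent, 32 loss, 33 age maps

tail(conservation_table(prod), 3)
#>    year extent extent_prev loss increment residual
#> 30 2016   1129        1125   35        39        0
#> 31 2017   1153        1129   17        41        0
#> 32 2018   1174        1153   26        47        0

truth_check(prod, sim$truth_ages)   # engine vs simulator ground truth
#> [1] 0

age18 <- prod$ages[["2018"]]
age18
#> <age_raster> year 2018, 60 x 60, 0 nodata px, value range [0, 33]

cumulative_uptake(age18)
#>      mean        sd
#> 4345.2945  270.6953
```

The 2018 extent holds 1,174 pixels (1.057 km² at 0.09 ha per pixel), and the
age map's pixels have accumulated 4,345 ± 271 Mg C under the capped linear
uptake model. Comparing the 2018 extent against the 2008 extent on 10-pixel
cells:

```r
tab <- grid_proportions(prod$extents[["2018"]], prod$extents[["2008"]], 10L)
bootstrap_compare(tab, n_iter = 1000, frac = 0.5, seed = 1)
#> <bootstrap_result> 1000 iterations, 50% of 36 cells, seed 1
#>   r2          0.3913 +/- 0.1557
#>   slope       0.6905 +/- 0.1764
#>   intercept  14.4691 +/- 4.6685
#>   rmse        3.2462 +/- 0.6514

mann_whitney(tab$prop_a, tab$prop_b)
#> <mann_whitney> W = 1,113, p = 1.58e-07 (normal approximation); ...
```

i.e. ten more years of regrowth raised the mean cell proportion from 26.3%
to 32.6%, a shift the rank test detects decisively.

A command-line wrapper with `simulate`, `run-all`, `reclassify`, `carbon`,
`validate` and `summarize` subcommands lives at
`system.file("cli", "regrow.R", package = "regrowmap")`:

```sh
Rscript regrow.R simulate --out-dir sim --seed 7
Rscript regrow.R run-all  --stack-dir sim --water sim/water_max.tif --out-dir products
Rscript regrow.R carbon   --age products/age_2018.tif --out carbon.csv
```

Class stacks are discovered as `*_YYYY.tif` files; legends are YAML blocks
(`forest: [3]`, `anthropic: [...]`, `excluded_forest: [...]`, `nodata: 0`).

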
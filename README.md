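# phenomaize

Phenology-based maize mapping from NDVI time series, for agricultural
remote-sensing analysts who need a tested, reproducible implementation of
the time-weighted dynamic time warping (TWDTW) crop-classification pipeline
and its full validation tool-chain — without terabytes of imagery: a
synthetic-landscape generator with known ground truth exercises every stage.

## The method

Each pixel's annual NDVI series $X=\{x_1,\dots,x_n\}$ is compared against a
standard seasonal maize curve $Y=\{y_1,\dots,y_m\}$ (the average of 50
randomly drawn maize samples) by dynamic time warping with an additive
logistic time penalty:

$$d_{base}(i,j)=\omega_{i,j}+|x_i-y_j|,\qquad
\omega_{i,j}=\frac{1}{1+e^{-\alpha(g(t_i,t_j)-\beta)}},$$

$$d_{i,j}=d_{base}(i,j)+\min\{d_{i-1,j},\,d_{i-1,j-1},\,d_{i,j-1}\},$$

with $g$ the elapsed days between aligned observations and defaults
$\alpha=0.1$/day, $\beta=50$ days, so warps beyond ~50 days are heavily
penalized. Classification then proceeds per region and year:

1. mask pixels whose NDVI never exceeds 0.3 in the growing window;
2. score the rest against the spring and/or summer maize curve, keeping the
   closer season;
3. select the $n$ lowest-distance pixels, where $n$ converts the region's
   statistical planting area into pixels — the identified area matches the
   statistic to within one pixel.

Validation covers confusion-matrix accuracies (PA/UA/OA under the
rows=identified, columns=surveyed convention, with conventionally named
precision/recall alongside), county-level agreement
($R^2$, RMAE, regression slope of identified on statistical area),
patch-size/fragmentation analysis (small ≤ 10 px, large > 1000 px, classes
I/II/III at 15% and 30% small-patch share) and multi-year
planting-frequency maps.

## Worked example

```r
library(phenomaize)

cfg  <- landscape_config(nrow = 100, ncol = 100, noise_sd = 0.02)
land <- generate_landscape(cfg, seed = 42)
land$stats
#> # A tibble: 1 × 3
#>   region    year area_ha
#>   <chr>    <dbl>   <dbl>
#> 1 region01  2019     315

res <- classify_region(land$stack, land$samples, land$stats,
                       run_config(seed = 7))
res$records
#> # A tibble: 1 × 7
#>   region    year statistical_area_ha identified_area_ha n_pixels n_candidates
#> 1 region01  2019                 315                315     3500         7500

cm <- confusion_from_samples(res$map, res$validation_samples)
accuracy_metrics(cm)
#> # A tibble: 1 × 7
#>      pa    ua    oa ua_other pa_other precision recall
#> 1   100   100   100      100      100       100    100

fragmentation_stats(patch_sizes(res$map))
#> # A tibble: 1 × 4
#>   n_patches small_patch_proportion large_patch_proportion fragmentation_class
#> 1        93                  0.828                 0.0108 III
```

The generator emitted a landscape whose maize truth area is 315 ha; the
area-constrained selector identified exactly that area (3500 pixels of
900 m²), and on the held-out validation samples the map is error-free —
at noise sd 0.02 the six synthetic phenologies remain fully separable, so
this run also matches the truth map pixel for pixel. The fragmentation
summary describes the patch structure of the resulting map (many small
field patches, class III).

A command-line wrapper with `simulate`, `build-refs`, `classify`,
`validate`, `county-agreement`, `patches`, `frequency` and `score`
subcommands is installed at
`system.file("cli", "phenomaize", package = "phenomaize")`.

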
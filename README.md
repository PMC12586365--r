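# rhizodyn

Seasonal growth dynamics and resource allocation of rhizomatous clonal
grasses monitored across patches of different sizes.

Clonal dune grasses expand as discrete patches: aboveground clusters of
shoots gain height and leaf area in a short unimodal burst, while the
belowground rhizomes that extend the patch grow for most of the year in a
bimodal rhythm. `rhizodyn` turns a season of per-cluster monitoring data
into the quantities ecologists compare across patch sizes:

* **Growth-curve fitting** — three fixed families on the day-of-year axis:
  power logistic for plant height,
  `y = A2 + (A1 - A2)/(1 + (t/x0)^p)`;
  BiHill (activating × inhibitory Hill terms) for leaf area,
  `y = Pm / ((1 + (Ka/t)^Ha)(1 + (t/Ki)^Hi))`;
  and a two-component base-10 sigmoid mixture for rhizome length,
  `y = A1 + (A2 - A1)[P/(1 + 10^((L1-t)h1)) + (1-P)/(1 + 10^((L2-t)h2))]`.
  Bounded multistart Levenberg-Marquardt least squares, adjusted R².
* **Phenology extraction** from the fitted curve and its analytic
  derivatives: maximum increment `W_max`, peak rate `V_max` and its date
  `D_vmax`, threshold onset/termination dates `D_o`/`D_t` (5%/95% of
  `W_max`), inflection-based rapid-growth window `D_r`-`D_st`, the derived
  periods `GD_sl`, `GD_r`, `GD_st`, `GD`, `V_mean = W_max/GD`, and a full
  second-phase set for bimodal rhizome fits.
* **Group statistics** — Brown-Forsythe homogeneity check routing to
  classic ANOVA + LSD or Welch ANOVA + Games-Howell, with compact letter
  displays.
* **Allocation** — trait-pair increment ratios (LA-PH, RL-LA, RL-PH) and
  standardized major axis (SMA) allometry `lg y = lg a + b lg x` with a
  slope-versus-isometry test (`b = sign(r)·sd(y)/sd(x)`; rotation-score F
  test of `b ≠ 1`).
* **Synthetic campaigns** — a seeded generator emulating the monitoring
  design (five patches from 0.51 to 36,075 m², 5-day aboveground and
  10-day rhizome survey calendars, sexual clusters only in the largest
  patch), so the whole pipeline is testable without field data.

## Worked example

```r
library(rhizodyn)

res <- run_pipeline(pipeline_config(seed = 1))
print(res)
#> <pipeline_result>
#>   series: 96 in, 96 converged, 0 failed
#>   seed 1 | simulated: TRUE
#>   tables: phenology (96 rows), sma (15 rows), ratios (15 rows)
```

`res$phenology` holds one row per monitored series. Population means by
trait show the staggered seasonal program — height peaks first, then leaf
area, then rhizomes, whose total growth period is by far the longest:

```r
aggregate(cbind(D_vmax, D_t, GD) ~ trait, res$phenology,
          function(x) round(mean(x), 1))
#>            trait D_vmax   D_t    GD
#> 1      leaf_area  134.2 193.0 106.0
#> 2   plant_height  103.0 147.3  63.2
#> 3 rhizome_length  162.7 273.8 176.9
```

The population-level comparison of total growth period routes to Welch's F
(variances differ between traits) and letters the groups from the largest
mean:

```r
print(res$trait_comparison$GD)
#> <group_comparison> GD [welch+games_howell]
#>   leaf_area        105.99 +/- 6.69 b (n=31)
#>   plant_height      63.23 +/- 8.96 c (n=31)
#>   rhizome_length   176.90 +/- 16.20 a (n=34)
#>   F = 649.194 (df 2, 58.4), p = 1.288e-40 *
```

Belowground-aboveground allocation rises with patch size in the simulated
campaign (ratio of patch-mean maximum increments, rhizome length over
plant height):

```r
subset(res$ratios, pair == "RL-PH")
#>     pair patch_area_m2    ratio
#> 3  RL-PH          0.51 1.374795
#> 6  RL-PH          2.29 1.660325
#> 9  RL-PH        201.11 2.476367
#> 12 RL-PH        312.93 2.583369
#> 15 RL-PH      36075.00 2.233890
```

`res$sma` mirrors the allometry summary (slope, intercept, R², p, and the
slope-vs-1 statistics per trait pair and patch); `res$manifest` records the
seed, configuration, and a reconciliation of series in = converged +
failed. Real campaigns are read from a long-format CSV
(`read_monitoring_table()`; columns `date`, `patch_area_m2`, `series_id`,
`type`, `trait`, `value`) and run with
`run_pipeline(config, input = "campaign.csv")`. A thin command-line wrapper
lives at `inst/scripts/run_pipeline.R`.

A published-arithmetic spot check: the micro-patch mean maximum height
increment of 76 cm over its 73-day growth period gives

```r
round(mean_growth_rate(76, 73), 1)
#> [1] 1
```

i.e. 1.0 cm/day at the printed precision.

## Documentation

The methods vignette (`vignettes/growth-dynamics-methods.Rmd`) documents
the model families and their assumptions, the phenology definitions and
thresholds, the generator calibration, and the package's numerical choices
and known limitations.
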
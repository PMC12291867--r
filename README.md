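# betadrivers

Tools for quantifying **beta diversity** — the variation in community
composition among sites — and for attributing it to landscape,
water-quality and spatial drivers. The package grew out of river
macroinvertebrate monitoring (sites sampled across regions and seasons,
paired with land-use rasters and physicochemical profiles) but applies to
any site-by-taxon count data.

It implements, as one tidyverse-style pipeline:

* **Partitioned dissimilarity** — pairwise and multi-site Sørensen
  (β_sor = β_sim + β_nes: turnover + nestedness) and Bray–Curtis
  (d_BC = d_BC-bal + d_BC-gra: balanced variation + abundance gradient)
  families, with group summaries.
* **Landscape drivers in circular buffers** — class proportions, LPI,
  CONTAG, SHDI (FRAGSTATS conventions) and the human-activity intensity
  index HAILS from ESRI ASCII land-use grids.
* **Weighted water-quality index (WQI)** — configurable normalization
  curves, weights and quality classes.
* **OPGD scale selection** — geographical-detector q-statistic
  (q = 1 − SSW/SST) with optimal discretization (five methods × 3–7
  classes, exact Fisher–Jenks among them) and the buffer radius chosen
  where the 90th percentile of the 11 driver q-values peaks.
* **Generalized dissimilarity modelling (GDM)** — monotone order-2
  I-spline transforms, the 1 − exp(−η) link, non-negative IRLS fitting,
  percent deviance explained, relative contributions and partial
  responses; `tidy()`, `glance()`, `autoplot()` methods included.
* **Null-model stochasticity** — the proportional-frequency,
  fixed-richness ("PF") randomization with Bray–Curtis, and the ST / NST /
  MST ratios; MST > 0.5 classifies a site pair as
  stochasticity-dominated.
* **A synthetic study generator** — landscapes, water quality and
  metacommunities with known ground truth (true buffer scale r*, niche
  strength λ, dispersal length δ), so every estimator has a
  parameter-recovery test.

## Worked example

Generate a synthetic survey (50 sites, 3 regions, 69 taxa, mixed
niche/dispersal assembly with λ = 0.7), then run the three main analyses:

```r
library(betadrivers)

study <- gen_study(synth_spec(lambda = 0.7), seed = 42)
cm <- study$communities$April

multisite_sorensen(cm)
#> # A tibble: 1 × 3
#>   beta_SOR beta_SIM beta_SNE
#>      <dbl>    <dbl>    <dbl>
#> 1    0.659    0.493    0.166

beta <- pairwise_sorensen(cm)
component_summary(beta, dplyr::select(study$sites, site_id, group = region))
#> # A tibble: 3 × 8
#>   group n_sites n_pairs mean_dissimilarity mean_similarity mean_turnover ...
#> 1 CAZ        14      91             0.0885           0.911        0.0599
#> 2 SMA        20     190             0.0826           0.917        0.0383
#> 3 YRIA       16     120             0.0566           0.943        0.0231
```

Overall dissimilarity across all 50 sites is substantial (β_SOR = 0.66)
and mostly turnover (β_SIM/β_SOR ≈ 75%), while within-region pairs remain
similar — composition changes between regions more than inside them.

```r
fit <- fit_gdm(build_sitepair_table(beta, list(
  geographic      = geodesic_distance_matrix(study$sites),
  altitude        = altitude_distance_matrix(study$sites),
  physicochemical = env_dissimilarity(study$env_by_month$April))))

glance(fit)
#> # A tibble: 1 × 6
#>   intercept deviance null_deviance explained converged iterations
#> 1    0.0554     14.8          33.3      55.5 TRUE               4

predictor_contributions(fit)
#> # A tibble: 3 × 3
#>   predictor       height contribution
#> 1 geographic       0                0
#> 2 altitude         0                0
#> 3 physicochemical  0.181          100
```

With λ = 0.7 the assembly is mostly environmental filtering, and the GDM
correctly attributes all of the explained compositional variation (55.5%
of deviance) to physicochemical dissimilarity rather than to geographic or
altitude distance. `autoplot(fit)` draws the monotone partial responses.

```r
ens <- null_model_pf(cm, R = 250, seed = 42)
stochasticity_summary(mst_pairwise(ens),
                      dplyr::select(study$sites, site_id, group = region))
#> # A tibble: 3 × 6
#>   group n_sites n_pairs mean_mst stochastic_share deterministic_share
#> 1 CAZ        14      91    0.672             78.0               22.0
#> 2 SMA        20     190    0.754             87.4               12.6
#> 3 YRIA       16     120    0.818             95.8                4.17
```

Mean MST below 1 in every region shows deterministic structure relative to
the PF null model, strongest in the CAZ region (lowest mean MST, largest
deterministic share of pairs).

For scale selection, stack `driver_table()` over candidate radii and pass
the mean WQI:

```r
drivers <- dplyr::bind_rows(lapply(study$spec$radii, function(r)
  driver_table(study$grid, study$sites, r)))
wq <- wqi(study$env, example_wqi_params())
buffer_scale_selection(drivers, wqi_mean(wq))
```

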
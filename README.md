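# nestmove

Movement-based tests of nest-site habitat sampling in nesting wild turkeys
(*Meleagris gallopavo*), for movement ecologists working with GPS telemetry
of ground-nesting birds.

The habitat-sampling hypothesis holds that a female evaluates candidate nest
areas during the weeks before laying, so her prenesting movements should
concentrate progressively near the eventual nest site. `nestmove` turns that
prediction into a testable movement analysis:

1. **Phase delineation.** From raw fixes, incubation onset is the first day
   on which every GPS location falls within a 50-m buffer of the nest (and
   that opens a run of ≥ 2 such days); laying is the preceding run of daily
   nest visits with the midnight roost elsewhere; prenesting is the 45 days
   before laying, indexed by days-before-laying 1…45.
2. **Range estimation.** Prenesting ranges are dynamic Brownian bridge
   utilization distributions (motion variance σ²ₘ estimated by leave-one-out
   maximum likelihood in sliding windows); incubation ranges are fixed
   bivariate kernels. Isopleths (50/75/95/99%) come with areas and nest
   membership.
3. **Nest-associated buffers.** Five individual-specific regions around each
   nest: the equal-area circle of the 95% incubation kernel
   (r = √(A/π)), the 75% incubation-kernel polygon, a circle at the
   population mean incubation distance (Rio Grande 70.82 m, Eastern
   55.24 m), and fixed 100- and 500-m circles.
4. **Inference.** Every hourly prenesting path segment is classified 0/1
   against each buffer; the pooled logistic model
   `logit P(hit) = β₀ + β₁ · day_before_laying` and windowed contingency
   odds ratios (days 1–5 vs 6–15 vs 16–45, Woolf 95% CIs) quantify whether
   interactions rise as laying approaches. Bird-clustered robust standard
   errors are available because consecutive segments of one female are
   serially dependent.
5. **Synthetic data.** A truth-tagged correlated-random-walk simulator
   reproduces the monitoring design (hourly fixes 0600–2000 plus a midnight
   roost fix, laying visits, stationary incubation, GPS error) with a
   `habitat_sampling` switch that creates the two worlds the test must
   distinguish.

## Worked example

Simulate six females that *do* sample habitat, run the pipeline, and test
for the signal:

```r
library(nestmove)

cfg <- sim_config(n_birds = 6, seed = 42, habitat_sampling = "sampling")
pop <- simulate_population(cfg)
bundle <- run_pipeline(pop$tracks, pop$nests, subspecies = "rio_grande",
                       fit_ranges = FALSE)

bundle$summary[, c("band_id", "days_prenest", "mean_dist_m",
                   "min_dist_m", "day_closest")]
#>   band_id days_prenest mean_dist_m min_dist_m day_closest
#> 1  SIM001           45       814.3      6.961          12
#> 2  SIM002           45       857.2      2.230           1
#> 3  SIM003           45       776.4      2.945           7
#> 4  SIM004           45       814.1      7.199          29
#> 5  SIM005           45       786.2      4.794          18
#> 6  SIM006           45      1072.1      6.913          14

fit <- bundle$logistic$fixed_100m
fit$coef[["b1"]]                  # -0.0426  (p = 1e-13)
predict_probability(fit, 1)       # 0.110
bundle$odds$w1_vs_w2$or           # 1.35  (95% CI 0.90-2.03)
```

Each row is one female's prenesting summary: tracked prenesting days, mean
and minimum distance (m) from the eventual nest over all prenesting fixes,
and the days-before-laying on which she came closest. The negative slope
(−0.043 per day-before-laying) says interactions with the 100-m nest buffer
become more likely as laying approaches — the signature the simulator was
asked to plant. With `habitat_sampling = "none"` the slope is statistically
indistinguishable from zero.

The published per-bird prenesting summaries for the two field populations
ship in `inst/extdata/` and feed the same aggregation engine:

```r
table_aggregates(read_published_summary("rio_grande"))
# mean prenesting days 42.38, mean distance 1636.05 m,
# mean minimum distance 166.46 m, 81% of nests outside the 50% core,
# day-closest counts 14 / 4 / 3, mean day 7.62
```

## Analysis workflow

Numbered drivers under `analysis/` run the full study shape end to end and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_populations.R` | two study-like null populations + a sampling-on control |
| `02_delineate_phases.R` | movement-only onset detection, scored against truth |
| `03_run_pipeline.R` | ranges, buffers, summaries, segment classification |
| `04_inference_report.R` | logistic fits, odds ratios, Welch test, figures |
| `05_published_table_aggregates.R` | footers recomputed from the published per-bird tables |

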
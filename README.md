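# navelopt

Links orchard environment to navel orange fruit quality, and turns the fitted
relationships into optimal environmental-factor ranges.

Orchard surveys in the Gannan production area record, per orchard, 16
environmental factors — annual precipitation and temperature (C1, C2),
elevation and slope (T1, T2), and twelve soil properties (S1–S12: pH, clay,
SOM, hydrolyzed N, total P, Olsen P, CEC, available K/B/Zn, exchangeable
Ca/Mg) — alongside 12 fruit-quality traits (Y1–Y11 plus TSS: weight,
diameters, shape index, CIELAB peel color, titratable acid, solid–acid
ratio, vitamin C). The package implements the full analysis chain such a
survey calls for:

1. **Descriptive statistics** — per-variable max/min/mean/SD, coefficient of
   variation, and a low/moderate/high variability class.
2. **Correlation screening** — Pearson matrix with p-values from
   t = r·√((n−2)/(1−r²)) and the usual `*` (p ≤ 0.05) / `**` (p ≤ 0.01)
   marks.
3. **PLSR with VIP selection** — single-response NIPALS partial least
   squares on the autoscaled factors; variable importance for the
   projection, VIPⱼ = √(p·Σₐ SSYₐ w²ₐⱼ / Σₐ SSYₐ); factors with VIP > 1.0
   are retained per trait.
4. **Equation fitting** — OLS refit of each trait on its retained factors,
   reported with R², the overall F = (R²/k)/((1−R²)/(n−k−1)) and its
   p-value.
5. **Linear programming** — for each trait in turn, optimize its equation
   (maximize, or minimize for shape index Y4 and titratable acid Y9)
   subject to every other trait staying at least as good as the survey mean
   and each factor confined to [survey mean, survey max]; the per-factor
   values across all programs give the optimal-range table.

A packaged equation system and bounds for the Gannan core production area
ship with the package, so the optimization stage runs without any raw data.
Because the underlying field data were never released, a seeded synthetic
generator (Gaussian copula over truncated-normal marginals, traits generated
from the packaged equations plus calibrated noise) stands in for them; it
drives the test suite and the end-to-end pipeline.

## Worked example

```r
library(navelopt)

# simulate a 99-orchard survey and screen titratable acid (Y9)
d  <- make_study_like_dataset(n = 99, seed = 42)
sr <- plsr_screen(d, "Y9")
sr$selected
#> [1] "S1" "S2" "S9"
round(sort(compute_vip(sr$fit), decreasing = TRUE)[1:4], 2)
#>   S1   S9   S2   S6
#> 1.94 1.78 1.36 0.98
```

pH (S1) and available B (S9) dominate the acidity model — VIP well above the
1.0 importance cut-off — so they are the factors the OLS refit keeps.

```r
# optimize every trait over the packaged equation system
res <- optimize_all(table4_equations())
round(sapply(res$solutions, function(x) x$objective_value), 2)
#>     Y1     Y2     Y3     Y4     Y5     Y6     Y7     Y8     Y9    Y10    Y11
#> 443.19  85.65  97.03   0.88  76.25  18.74  56.43   1.48   0.49  26.20  57.27

res$solutions[["Y9"]]
#> <lp_solution> Y9: optimal, objective 0.4892

subset(res$range_table, code %in% c("S1", "S3", "S12"),
       select = c(code, range_lower, range_upper))
#>    code range_lower range_upper
#> 5    S1       4.840        7.50
#> 7    S3      21.330       36.73
#> 16  S12       2.762        4.00
```

Each column of the range table is the factor vector at one trait's optimum;
the range rows read as recommendations: acidity is minimized at 0.49 % TA
with pH pushed to its observed maximum of 7.5, while SOM between 21.3 and
36.7 g/kg keeps every quality trait at or above the survey average.

The single entry point `run_pipeline(pipeline_config(...))` chains all five
stages (from a CSV of coded columns, or from the simulator) and can write
the summary tables, correlation matrices, equation system, range table and
a markdown report to a directory.

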
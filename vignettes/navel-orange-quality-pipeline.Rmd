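---
title: "From orchard environment to optimal fruit-quality ranges: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From orchard environment to optimal fruit-quality ranges: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navelopt)
```

## The problem and the modeling chain

Navel orange quality — fruit weight, the two diameters and their ratio
(shape index), CIELAB peel color (L\*, a\*, b\*, hue angle), titratable acid,
the solid–acid ratio and vitamin C — responds to the orchard's climate,
topography and soil chemistry. Given a samples × variables table (orchards
in rows; 16 environmental factors and 12 quality traits in columns), the
package runs a five-stage chain:

1. descriptive statistics with a variability classification;
2. Pearson correlation screening with two-level significance marks;
3. per-trait partial least squares regression (PLSR) and VIP-based variable
   selection;
4. ordinary least squares (OLS) refit of each trait on its selected factors,
   yielding one linear equation per trait with an overall F test;
5. linear programming (LP) over the equation system to locate the factor
   settings under which every trait meets at least its survey average while
   one trait at a time is pushed to its best value.

The factor and trait codes (`C1`–`C2`, `T1`–`T2`, `S1`–`S12`,
`Y1`–`Y11`, `TSS`) are fixed by `variable_registry()`; `TSS` carries no
optimization sense and no equation (no factor passes VIP screening for it),
so eleven traits are modeled.

## PLSR, VIP and the component rule

Factors span wildly different units (mm of rain to mg/kg of zinc), so both
blocks are autoscaled (centered, unit variance) before NIPALS. For a single
response each component is exact in one pass: the weight vector is the
normalized covariance $w_a = X_a^\top y_a / \lVert X_a^\top y_a\rVert$,
scores $t_a = X_a w_a$, Y-loading $q_a = t_a^\top y_a / t_a^\top t_a$,
followed by deflation of both blocks. Variable importance for the
projection is

$$\mathrm{VIP}_j = \sqrt{\,p\,\frac{\sum_a \mathrm{SSY}_a\, w_{aj}^2}
{\sum_a \mathrm{SSY}_a}\,},\qquad \mathrm{SSY}_a = q_a^2\, t_a^\top t_a,$$

so the mean squared VIP is exactly 1 and the conventional cut-off
"important if VIP > 1.0" (strict inequality) reads as "above average
importance". Two consequences worth keeping in mind:

* With $p = 16$ predictors and only a handful truly active, VIP > 1 keeps
  the dominant members of the active set but *must* drop below-average
  ones — a generating term like $0.001\,S_{11}$ in the acidity equation is
  undetectable by construction. Screening recovers the dominant active
  factors, not every nonzero coefficient.
* Contribution percentages are reported as $100\,\mathrm{VIP}_j^2 / p$;
  they sum to 100 and are additive over factor subsets, which is what makes
  category totals (e.g. "soil contributes 45 %") well defined. The exact
  importance measure used in the original figure captions is not specified
  anywhere, so this normalized squared VIP is the package's own documented
  choice.

The number of components defaults to the smallest $A$ whose cumulative
explained share of the response variance reaches 90 % (capped at
$\min(n-1, 16)$). A deterministic rule was preferred over cross-validation
because it makes every downstream artifact reproducible from the seed
alone; `plsr_screen(..., components = )` overrides it.

## Equation fitting

Traits are refit by OLS on their VIP-selected factors because the classical
overall test
$F = (R^2/k)\,/\,((1-R^2)/(n-k-1))$, with $p$ from the
$F_{k,\,n-k-1}$ distribution, is an OLS construct; PLS regression
coefficients carry no such test. Traits whose screening selects nothing are
dropped from the system with a warning, which keeps the optimization stage
well posed. Coefficients are stored at full double precision; report
rendering rounds to 3 decimals.

A packaged `equation_system` for the Gannan core production area ships in
`inst/extdata/` together with the published overall F statistics of its
eleven equations; its provenance tag is `"packaged-table-4"` and the fitted
systems produced by `build_system()` are tagged `"fitted"`.

## The linear programs

For a target trait the LP is: optimize its equation (maximize, or minimize
for shape index `Y4` and titratable acid `Y9`, the two traits where smaller
is better) subject to

* every *other* modeled trait's equation held at its registered direction
  and bound — at least the survey mean for maximize-sense traits, at most
  the survey mean for the two minimize-sense ones;
* box constraints per factor: survey mean ≤ value ≤ survey maximum.

The target's own bound is omitted, mirroring the published example program.
`optimize_all()` solves all eleven programs and tabulates each factor
across the optima; the min–max per factor is the "optimal range".

The solver is a dense two-phase simplex with Bland's smallest-index
pivoting rule, written for exactly this problem scale (16 variables, ~26
constraints; all eleven programs solve in well under a second). Bland's
rule trades speed for guaranteed termination under the heavy degeneracy
these box-dominated programs exhibit. Tolerances: feasibility and binding
detection 1e-6 absolute; reports round to 2 decimals. The suite verifies
the solver against a brute-force vertex-enumeration oracle on random small
programs and checks every returned solution for feasibility and dominance
over 1000 rejection-sampled feasible points.

Two honest caveats about LP output:

* **Alternative optima.** A factor absent from the objective and from every
  binding constraint is arbitrary within its box at the optimum (clay `S2`
  appears in no equation at all). Such factors are listed in the solution's
  `nonunique` field; their tabulated values are vertex-dependent and only
  the objective value is canonical. The b\* program, for instance, leaves
  exchangeable Mg free: pinning it at its upper bound changes nothing about
  the optimum.
* **Rounded coefficients.** The packaged equations are printed at 3
  decimals; optima computed from them can differ in the second decimal from
  values computed with unrounded internals elsewhere.

## The synthetic-orchard generator

The original field data were not deposited, so `make_study_like_dataset()`
emulates them from the published summary tables:

* **Factors.** Each of the 16 factors is a normal with the published mean
  and SD, truncated to the published [min, max], coupled through a Gaussian
  copula. The default correlation is identity except for an exchangeable
  r = 0.4 block across the ten soil-nutrient variables (S3–S12), mimicking
  the reported strongly positive soil-nutrient correlations; no numeric
  correlation matrix was published, so only the structure is emulated.
* **Traits.** Each modeled trait is its packaged equation evaluated on the
  factors plus independent homoscedastic Gaussian noise. The default noise
  SD per trait is calibrated so the refit F statistic at the study size
  n = 99 lands near the published value: from $F$ and $k$ regressors,
  $R^2 = Fk/(Fk + n - k - 1)$, and the noise SD is
  $\mathrm{sd}(\hat\mu)\sqrt{(1-R^2)/R^2}$ on the realized factor draw.
  No residual variances were published, so this calibration is a documented
  heuristic. `TSS` is generated as a pure truncated-normal noise trait,
  unlinked to the factors.
* **Seeding.** One integer seed drives everything; the trait stream uses
  the seed offset by one so factors and traits can be regenerated
  independently. Identical configuration implies bit-identical output.

What the generator does *not* emulate — and hence what passing tests do not
show about real orchards: the marked right skew of several soil variables
(available Zn has survey CV 1.46; a truncated normal with those parameters
has a CV near 0.64, so simulated dispersion is milder than the field's),
spatial autocorrelation among neighboring orchards, heteroscedastic or
correlated trait residuals, and the published pairwise correlation values
themselves. Tests of marginal fidelity therefore compare simulated moments
against the *analytic truncated-normal targets*, not against the survey's
printed CVs.

## Numerical and degenerate-input choices

* Sample (n−1) standard deviations throughout.
* Variability classes: CV < 10 % low, 10–30 % moderate, > 30 % high. The
  survey's own prose labels are inconsistent, so this tripartition is the
  package's documented convention.
* Mean-splits send samples exactly at the threshold to the above-group.
* A constant response in `quadratic_trend()` gets $R^2 = 0$ (avoiding 0/0)
  and zero slope coefficients.
* Correlation p-values: boundary cases at exactly 0.05 or 0.01 receive the
  stronger mark; an exact |r| = 1 pair gets p = 0 rather than a failed
  t transform. No multiple-testing correction — marks are raw per-pair
  levels, as in the original correlation figure.
* Zero-variance columns error in correlation and PLSR (named in the
  message); in descriptive summaries they report SD 0, CV 0, class low.
* CSV I/O writes 17 significant digits so a write–read round trip is exact
  and rewriting is byte-identical; missing values are rejected, never
  imputed.

## Problem sizes used by the suite

Marginal-fidelity checks draw 10 000 orchards against analytic
truncated-normal moments (3 standard-error bands); calibration checks
average 20 seeds at the study size n = 99; screening-recovery checks run 20
seeds of n = 5000 at noise SD 0.05 and require the dominant acidity factors
{pH, available B, exchangeable Mg} to be selected in at least 90 % of
seeds; LP verification enumerates vertices on programs of up to 6
variables. The whole suite and the acceptance script each run in well under
a minute on one CPU.

## Limitations

The equation system is linear by design; curvature found in the
single-factor explorations (the second-order trends against elevation and
slope) does not enter the optimization. LP optima sit at polytope vertices,
i.e. they inherit every defect of the fitted equations at the boundary of
the observed factor range, and say nothing about extrapolation beyond the
survey's maxima. The published per-trait component counts and p-values
cannot be re-derived without the raw field data; only the formula paths are
testable, and the packaged system is reproduced digit-for-digit instead.
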
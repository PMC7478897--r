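---
title: "Methods: comparing MDD-7 and MDD-8 from complex survey microdata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing MDD-7 and MDD-8 from complex survey microdata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddcompare)
```

## The two indicator definitions

Minimum dietary diversity (MDD) is a population-level dietary quality
indicator for children aged 6–23 months, based on a 24-hour recall of
food-group consumption. Two definitions are in circulation:

* **MDD-7**: the proportion of children who consumed **≥ 4 of 7** food
  groups (grains/roots/tubers; legumes and nuts; dairy; flesh foods;
  eggs; vitamin-A-rich fruits and vegetables; other fruits and
  vegetables). Breastmilk does not count.
* **MDD-8**: the proportion who consumed **≥ 5 of 8** groups, where
  breastmilk is the eighth group.

Writing $S_7 \in \{0,\dots,7\}$ for the 7-group count and $B \in \{0,1\}$
for breastmilk consumption, the scores satisfy $S_8 = S_7 + B$, so a child
meeting MDD-8 ($S_8 \ge 5$) always meets MDD-7 ($S_7 \ge 4$). Population
MDD-8 prevalence therefore never exceeds MDD-7 prevalence, and the
arithmetic difference in percentage points (`difference_pp()`, MDD-8 minus
MDD-7) is never positive. How large the gap is depends on how many
children sit exactly at $S_7 = 4$ without breastmilk — which is why
populations where breastfeeding stops early in the second year of life
show the largest gaps. The thresholds are deliberately **not**
configurable: the package's subject is precisely this definitional change,
and a silent cut-off drift would defeat it.

## Design-based estimation

National feeding surveys use stratified multi-stage cluster designs with
sampling weights. For an outcome $y_i$ with weights $w_i$ the package
estimates the ratio $\hat p = \sum w_i y_i / \sum w_i$ and obtains its
variance by first-stage Taylor linearization: with linearized variate
$z_i = w_i (y_i - \hat p) / \sum w$, cluster totals
$Z_{hc} = \sum_{i \in hc} z_i$, and $n_h$ clusters in stratum $h$,

$$\widehat{\mathrm{Var}}(\hat p) \;=\; \sum_h \frac{n_h}{n_h - 1}
  \sum_c \left(Z_{hc} - \bar Z_h\right)^2 .$$

With one implicit stratum, independent records as their own PSUs and
equal weights this collapses to the simple-random-sampling formula
$\sqrt{p(1-p)/(n-1)}$, which the test suite asserts exactly.

Numerical and design choices:

* **Confidence intervals.** 95% intervals default to the logit-transformed
  form ($\mathrm{logit}\,\hat p \pm 1.959964\,\widehat{se}/[\hat p(1-\hat p)]$,
  back-transformed), which respects $[0,1]$ and matches common survey
  software conventions; a symmetric Wald interval is available by flag.
  The normal quantile is used rather than a $t$ quantile because PSU
  counts in these surveys are large (hundreds of clusters). Constant
  outcomes give SE 0 and a point interval.
* **Subgroups as domains.** Age-band estimates (6–11, 12–23 months) keep
  the full design and zero the linearized variate outside the band rather
  than subsetting records: the point estimate equals the naive subset
  ratio, but the SE correctly reflects the design.
* **Singleton-PSU strata** raise an explicit error by default; a
  `singleton = "centered"` fallback (deviation from the grand PSU mean)
  is available but never silent, since lone PSUs usually signal design
  mis-specification.
* **Scale invariance.** Only relative weights matter; every estimate, SE
  and CI is invariant to rescaling all weights.

Out of scope: replicate-weight (BRR/bootstrap) variance,
finite-population corrections, and variance stages beyond the first-stage
between-PSU approximation. The delete-one-cluster jackknife appears only
as an independent test oracle, not as an estimation option.

## Age smoothing

The package draws lowess curves of breastfeeding, MDD-7 and MDD-8 status
against age in months, unweighted (they describe the sample's age
pattern, not a design-based estimate). Because "lowess" names a family of
smoothers, one variant is pinned so outputs are reproducible:

* at each evaluation age $x_0$, the $\lceil f \cdot n \rceil$ nearest
  observations by $|age - x_0|$ are selected, distance ties all included
  ($f$ = bandwidth, default 0.7);
* tricube weights $(1 - (d/d_{\max})^3)^3$ on distance normalised by the
  largest selected distance;
* a weighted least-squares line, evaluated at $x_0$;
* no robustness iterations;
* the evaluation grid is the distinct observed ages (monthly data
  granularity), and the 0/1 microdata are smoothed directly rather than
  pre-aggregated to monthly proportions — that is what lowess on
  microdata does, and whether published analyses smoothed microdata or
  aggregates is generally unstated.

Degenerate cases are defined, not accidental: a neighbourhood whose
selected points all sit at $x_0$ (or whose positive-weight points share
one age, detected at relative tolerance $10^{-10}$ on the weighted
$x$-variance) falls back to the weighted mean; all-identical ages are an
error; local linear fitting reproduces exactly linear data to machine
precision, which the tests assert at $10^{-10}$. Smoothing is not
monotone-preserving in general, so the dominance MDD-8 ≤ MDD-7, exact in
the raw per-age proportions, is asserted for smoothed curves only on
well-behaved fixtures at tolerance $10^{-6}$.

## The synthetic cohort generator

Registered-access survey microdata cannot ship with a package, so every
downstream stage is validated against a generator whose population truth
is known. `mdd_scenario()` describes:

* a stratified cluster design: clusters assigned round-robin to strata,
  Poisson cluster sizes (minimum 1) to exercise the variance estimator
  with unequal clusters, gamma-distributed weights with mean 1 and
  configurable coefficient of variation (positive and right-skewed, like
  real design weights);
* logistic age curves for breastfeeding,
  $P(B = 1 \mid a) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 a)$, and for
  each food group,
  $P(G_g = 1 \mid a, u) = \mathrm{logit}^{-1}(\gamma_g + \delta a + u)$,
  with a shared child-level latent propensity $u \sim N(0, \sigma^2)$
  on the food groups only. The latent shift induces the positive
  inter-group correlation real diets show while keeping the
  $\sigma = 0$ case exactly enumerable; surveys publish no joint model
  of breastfeeding and food groups, so breastfeeding is generated
  independently given age — a documented simplification;
* a uniform default age distribution over 6–23 months, and one record
  per child (the youngest-child-per-household selection is treated as
  already applied by the sampling frame; `dedupe_youngest()` exists for
  data where it is not).

`true_indicator_values()` evaluates the implied population quantities
exactly when $\sigma = 0$ (convolution of the seven Bernoulli indicators
age by age) and by Monte Carlo otherwise; the two routes agree within
sampling error, which is itself a test.

### Preset calibration

Two presets pin the generator to contrasting published regimes, using
only the cited moments as targets: `"high-bf-low-diversity"`
(continued breastfeeding at 12–23 months ≈ 79.3%, mean 7-group score
≈ 1.8) and `"low-bf-high-diversity"` (≈ 34.7% and ≈ 3.5). Calibration
was done once, ahead of testing: the breastfeeding intercept and slope
solve the two age-band means of the logistic curve; a fixed intercept
pattern over the seven groups (grains most common, eggs least) is
shifted by a scalar, solved by root-finding with the latent
heterogeneity integrated numerically, to hit the mean-score target. The
per-month slope 0.08 and heterogeneity SD 0.9 were chosen a priori as
realistic for complementary-feeding data and are not tuned. Presets use
200 clusters of expected size 20 in 8 strata (≈ 4,000 children, typical
of a national survey's 6–23-month subsample) and weight CV 0.25.

What the generator does **not** emulate: non-response and calibration
adjustments to weights, within-cluster correlation beyond shared design
membership, seasonal recall effects, questionnaire-specific item
wording, or any specific country's strata counts. Passing tests
therefore show that the estimators and indicator algebra are correct
under a realistic design, not that any particular national estimate is
reproduced from its microdata.

## Ingest conventions

Delimited text with a header is read through an explicit column mapping
(`column_mapping()` or YAML via `read_mapping()`); item columns
aggregate to groups by OR. Conventions where practice varies:

* a missing single diet item reads as "not consumed"; a record is
  dropped only when *every* diet item (including breastmilk) is missing,
  the standard large-survey convention — all exclusions are counted by
  reason in the ingest report;
* truthy encoding defaults to `{1, yes}` with everything else
  (including missing codes) falsy, configurable per file;
* the breastmilk source column is named explicitly in the mapping rather
  than guessed, because questionnaires carry both a diet-module
  "breastmilk in previous 24 h" item and a "currently breastfeeding"
  status variable and the two differ;
* ages must be completed months in 6–23; proprietary survey binary
  formats are out of scope (export to delimited text first).

## Country comparison and reporting

`compare_country()` assembles the full row for one survey — age-band
breastfeeding, both MDD prevalences (percent scale), both mean scores,
the percentage-point difference, and a CI-overlap flag (closed
intervals: touching endpoints overlap). The difference is computed from
unrounded estimates and rounded to 1 decimal only for display; the
published worked-example rows are consistent with either computation
order at printed precision, so the choice is cosmetic but fixed.
`rank_differences()` ranks by absolute difference (robust to future
indicator revisions even though all current gaps share a sign) and
counts gaps strictly greater than 5 percentage points.
`write_comparison_table()` renders the conventional layout
(`"x.x (lo, hi)"`, `"m.m (se)"`) and `read_comparison_table()` parses it
back losslessly at printed precision.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
sc <- preset_scenarios()[["low-bf-high-diversity"]]
cohort <- generate_cohort(sc, seed = 1)
scores <- score_cohort(cohort)
cc <- compare_country(cohort, scores, year = "synthetic")
cc
plot(cc)
```

The reference rows for the fourteen published surveys are available as
worked-example inputs:

```{r reference}
rk <- rank_differences(esa_reference())
rk$largest
rk$n_gap_gt5
```

## Problem sizes and test design

The test suite validates estimator algebra on a packaged 30-record,
6-cluster, 3-stratum fixture against term-by-term brute-force oracles at
$10^{-10}$; convergence properties use generated cohorts of roughly
1,000–50,000 children; confidence-interval coverage uses 200 replicate
cohorts of ≈ 4,000 children from the calibrated presets, checked against
the nominal band [90%, 98%] around 95%. These sizes were chosen so the
whole suite runs in well under a minute while leaving Monte-Carlo error
far smaller than the assertion tolerances.

## Known limitations

* Variance estimation stops at the first-stage between-PSU
  approximation, as is standard for these surveys.
* The generator's independence of breastfeeding and food groups given
  age means it cannot represent populations where weaning itself shifts
  the complementary diet at fixed age.
* Smoothed curves carry no confidence bands, and robust (iterated)
  lowess is intentionally absent.
* Published national estimates are reproduced only as worked-example
  inputs; recomputing them requires the registered-access microdata.
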
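# mddcompare

Tools for computing and comparing the two minimum dietary diversity (MDD)
indicators for children aged 6–23 months from child-level survey
microdata, for nutrition analysts and survey statisticians tracking
infant and young child feeding (IYCF).

## The problem

MDD is a population-level dietary quality indicator built from a 24-hour
food-group recall. Its definition was updated from **MDD-7** — the
proportion of children consuming ≥ 4 of 7 food groups, breastmilk
excluded — to **MDD-8** — ≥ 5 of 8 groups, with breastmilk as the eighth
group. Writing S₇ for the 7-group count and B ∈ {0, 1} for breastmilk,

    S₈ = S₇ + B,   MDD-7: S₇ ≥ 4,   MDD-8: S₈ ≥ 5,

so MDD-8 ⇒ MDD-7 child by child and national MDD-8 prevalence is always
the lower of the two. The size of the drop varies by country — driven by
continued-breastfeeding rates in the second year of life — and a naive
reading of a trend series mixing the two definitions would see a spurious
"regression". This package makes the comparison explicit and testable:

* **scoring** of per-child diversity scores and both classifications;
* **design-based estimation**: weighted prevalences and means with
  Taylor-linearized variance under stratified cluster sampling,
  logit-transformed 95% CIs, and age-band domain estimation;
* **age smoothing**: reproducible tricube local-linear lowess curves
  (bandwidth 0.7) of breastfeeding, MDD-7 and MDD-8 by age in months;
* **country comparison**: assembled rows with the MDD-8 − MDD-7
  difference in percentage points, CI-overlap flags, gap ranking, and a
  formatted, round-trippable report table;
* **ingest** of delimited microdata through an explicit column mapping
  with item-to-group OR aggregation and an exclusion report;
* **synthetic cohorts**: a generator of DHS-like stratified cluster
  samples with exactly known population indicator values, so the whole
  pipeline is validated without registered-access microdata.

## Worked example

```r
library(mddcompare)

sc     <- preset_scenarios()[["low-bf-high-diversity"]]  # South-Africa-like
cohort <- generate_cohort(sc, seed = 1)
scores <- score_cohort(cohort)
cc     <- compare_country(cohort, scores, year = "synthetic")
cc
#> Dietary diversity comparison: low-bf-high-diversity synthetic (n = 3921, PSUs = 200)
#>   breastmilk, prev. 24 h:  6-11 mo 62.7 (60.0, 65.4)   12-23 mo 34.9 (33.1, 36.7)
#>   MDD-7 (>=4 of 7): 48.2 (46.6, 49.8)%,  mean groups 3.4 (0.03)
#>   MDD-8 (>=5 of 8): 37.4 (35.8, 39.0)%,  mean groups 3.9 (0.03)
#>   difference (MDD-8 - MDD-7): -10.8 pp; 95% CIs do not overlap
```

Reading the row: in this low-breastfeeding, relatively diverse-diet
scenario nearly half the children meet MDD-7, but a tenth of all
children sit at exactly 4 food groups without breastmilk, so the
switch to MDD-8 drops the headline prevalence by about 11 percentage
points and the two 95% CIs do not even overlap. `plot(cc)` draws the
smoothed age curves, which show the gap opening in the second year of
life as breastfeeding stops.

Published reference rows for 14 Eastern and Southern African surveys
ship as worked-example inputs:

```r
rk <- rank_differences(esa_reference())
rk$largest    # South Africa, -8.9 pp
rk$smallest   # Ethiopia,     -1.4 pp
rk$n_gap_gt5  # 3 countries with |gap| > 5 pp
```

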
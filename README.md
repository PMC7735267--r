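# migrcline

Statistical tools for studying **songbird migratory divides** from tracking
data. In central Europe, blackcap (*Sylvia atricapilla*) populations with
inherited southwest (SW) and southeast (SE) autumn migration directions meet
in a narrow contact zone near 14° E, where many birds take intermediate (S)
routes and a novel northwest (NW) strategy — wintering in Britain — has
recently spread. migrcline implements the downstream analyses such a study
needs, starting from coordinate tables (the package deliberately does not
process raw light-level data):

* **Phenotyping** — rhumb-line autumn direction from breeding and wintering
  sites; winter-longitude classification into SW / S / SE / NW; Levene
  (Brown–Forsythe) variance comparisons among sites with
  Benjamini–Hochberg adjustment; ANOVA-based repeatability of repeated
  tracks with a parametric-bootstrap CI.
* **Cline fitting** — maximum-likelihood fit of the tanh sigmoid cline

  μ(x) = μ_L + (μ_R − μ_L) · (1 + tanh(2(x − c)/w)) / 2

  to grouped directions along an east–west transect, with
  two-log-likelihood-unit support intervals from profile likelihoods and
  width conversion from degrees longitude to km.
* **Timing** — migration progress against 30/50/70% great-circle threshold
  lines; crossing times (with an optional seeded position-spread ensemble);
  duration (floored at one day), speed, equinox and late-winter exclusion
  rules; OLS timing-contrast models (SW−SE, S−mean(SW,SE), NW−SW) with
  backward covariate elimination at p > 0.10 via emmeans contrasts.
* **Assortative-mating simulation** — multinomial cohorts, per-phenotype
  arrival-date models, and timing-dependent mate choice within a 5-day
  presence window; reports the share of both-intermediate pairings.
* **Ringing-recovery filter** — directed southward movements from the
  breeding region, filtered on encounter box, seasonal windows, bearing
  (100–270°) and distance (≥ 500 km), with a per-criterion audit.
* **Synthetic data** — seeded generators for cohorts, geolocator-like daily
  tracks (latitude noise inflated near equinoxes), arrival dates and
  recovery records, with ground truth attached, so the whole pipeline is
  testable end to end.

See `vignettes/migratory-divide-methods.Rmd` for the models, assumptions,
parameter defaults and known limitations.

## Worked example

```r
library(migrcline)

# a synthetic divide cohort at the study conditions (pure function of seed)
cohort <- generate_divide_cohort(90, seed = 1)
prop.table(table(cohort$phenotype[cohort$zone == "divide"]))
#>    SW     S    SE    NW
#> 0.364 0.364 0.182 0.091

# group along the transect and fit the direction cline
groups <- make_groups(cohort$breed_lon, cohort$direction_deg, cohort$zone)
fit <- fit_cline(groups, seed = 1)
fit
#> Sigmoid cline fit (maximum likelihood)
#>   centre  14.000   2LL support [13.963, 14.052]
#>   width   0.315   2LL support [0.137, 0.499]
#>   asymptotes 241.4 -> 151.4 deg; sigma 18.33 deg
#>   log-likelihood -179.147 over 45 groups
lon_width_to_km(fit$params$width, mean(cohort$breed_lat))
#> [1] 23.6
```

The fitted centre sits on the generating cline centre (14.0° E) and the
width — here 0.315° longitude ≈ 24 km at the transect latitude — on the
generating 27 km, within the support interval. The mating simulation
contrasts timing-independent and timing-dependent mate choice:

```r
run_mating_sim(mating_config(timing_dependent = FALSE), seed = 1)
#> both-S pairings: mean 29.0% (SD 10.3), 95% interval [9.8%, 48.8%]
run_mating_sim(mating_config(), seed = 1)   # S birds arrive 8.9 d early
#> both-S pairings: mean 42.0% (SD 10.3), 95% interval [22.0%, 61.0%]
```

The timing-independent mean matches the analytic null p_S² = 0.537² ≈ 28.8%
for directed pairings; early arrival of intermediates raises assortment
well above it.

A thin command-line wrapper over the same functions lives at
`inst/cli/migrcline.R`:

```sh
Rscript inst/cli/migrcline.R all --out run1 --seed 7       # full pipeline
Rscript inst/cli/migrcline.R euring --recoveries recs.csv  # recovery filter
```

Recovery CSVs use a minimal EURING-style mapping: one row per
(ring, re-encounter) with columns `ring_id, date1, lat1, lon1, date2, lat2,
lon2` (ISO dates; encounter 1 is the ringing event).

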
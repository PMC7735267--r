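---
title: "Methods: cline fitting, timing and assortative-mating simulation for a songbird migratory divide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cline fitting, timing and assortative-mating simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrcline)
```

# Scope and data model

migrcline implements the downstream statistical analyses of a geolocator
study of a songbird migratory divide: the zone in central Europe where
blackcap populations with inherited southwest (SW) and southeast (SE) autumn
migration directions meet, with intermediate southerly (S) routes common in
the contact zone and a recently evolved northwest (NW) strategy wintering in
Britain. The package starts from *position tables* — per-bird breeding and
wintering coordinates, and daily position series of the kind produced by
light-level geolocation pipelines — not from raw light data; twilight
processing and particle-filter positioning are out of scope.

All coordinates are decimal degrees on a spherical Earth with
R = 6371.0088 km. Geolocator error dwarfs the sphere/ellipsoid difference,
so no ellipsoidal geodesy is used. Bearings are degrees clockwise from true
north in [0, 360). Standard geodesic steps (rhumb bearings and destinations,
haversine distances, great-circle interpolation) are delegated to the
geosphere package behind the exported wrappers; longitudes are always
differenced on the shortest arc, so the library behaves sensibly near the
antimeridian even though the study region (about 20° W to 52° E) never
approaches it.

# Migratory phenotyping

A bird's autumn direction is the rhumb-line (constant-compass) bearing from
its breeding to its wintering site — a deliberately simplified route summary
that is robust to track nonlinearity and equinox bias. Wintering locations
map to phenotypes by longitude cut-offs: north of 37.5° N, SW west of 5° E,
SE east of 20° E, S between; south of 37.5° N the SW/S boundary moves to 0°
because longer routes need less westerly component to reach the same
longitude. Two conventions the source rules leave open are fixed here and
are configurable in `classification_rule()`:

* **NW rule.** British winterers are defined by destination without a stated
  numeric rule; we use wintering latitude ≥ 45° N, which captures all
  British sites and no Mediterranean site.
* **Boundary ties.** A longitude exactly on a cut (within 1e-9°) belongs to
  S: the intermediate interval is closed, and labels are stable under
  sub-nanodegree perturbation.

Variance comparisons between breeding sites use the Brown–Forsythe form of
Levene's test (`car::leveneTest`, median-centred) with Benjamini–Hochberg
adjustment across site pairs. Because directions are angles, the response is
by default the signed angular deviation from each site's circular mean
(`deviations = "raw"` switches to plain degrees; in this study's direction
range, 130–290°, the two agree closely). Repeatability of repeated tracks is
the one-way ANOVA variance-components intraclass correlation with the
negative between-bird component truncated at zero; its confidence interval
comes from a seeded parametric bootstrap (1000 draws) rather than likelihood
profiling — simpler, and adequate at the study's tiny repeat sample.

# The direction cline

The core model is a tanh sigmoid cline in mean migration direction along an
east–west transect coordinate \(x\) (degrees longitude):

\[
\mu(x) \;=\; \mu_L + \big(\mu_R - \mu_L\big)\,
\frac{1 + \tanh\!\big(2 (x - c)/w\big)}{2},
\]

with centre \(c\) (the inflection), width \(w\) (inverse of the maximum
slope), asymptotic directions \(\mu_L, \mu_R\), and an individual direction
SD \(\sigma\). Group mean directions are modelled
\(\bar y_i \sim \mathrm{Normal}(\mu(x_i),\, \sigma/\sqrt{n_i})\); a single
global \(\sigma\) is estimated jointly (whether the original analysis used
per-group or global dispersion is not stated; global is the minimal
identifiable choice). Directions are treated as linear degrees, not circular
quantities: the observed range never wraps, and this is recorded as a known
limitation rather than handled with circular likelihoods. Exponential cline
tails are omitted — with on the order of 90 birds only centre and width are
identifiable.

Individuals are grouped before fitting: within each zone (west of, inside,
east of the divide — kept separate so the densely sampled divide is never
pooled with sparse tails), birds sorted by longitude are split into
contiguous groups of at least two, sizes as equal as possible with larger
groups placed eastward. This is a deterministic stand-in for quantile-based
binning; on tied longitudes it may split differently, which is why the
minimum group size is a parameter.

Fitting is bounded maximum likelihood (`optim` L-BFGS-B) with one
data-driven start plus four seeded random starts. The box constraints are
estimation-side choices: the centre must lie within the observed position
range and the width within the position span (a cline wider than the sampled
transect is unidentifiable), asymptotes within the observed trait range plus
a margin. A fit whose asymptotes coincide is flagged
`width_unidentifiable`. Uncertainty is reported as two-log-likelihood-unit
support intervals from profile likelihoods (grid re-maximisation over the
remaining parameters), matching the 2LL reporting convention for hybrid-zone
clines; no MCMC posterior is computed. Width in degrees longitude converts
to km as \(w \times 111.195 \times \cos(\text{lat})\) at the mean latitude
of the included sites (about 47.6° N here), and the conversion latitude is
recorded in the outputs.

# Migration timing

Progress along a migration is measured against the great-circle route from
breeding to wintering site. Threshold lines perpendicular to the route at
30%, 50% and 70% of its length mark early, middle and late migration; values
closer to the endpoints fail more often because local movements near the
summer and winter sites cross them repeatedly. Each track sample is
projected onto the route to a signed along-route fraction; crossing times
are linear interpolations at sign changes. A track that never crosses a
line, or crosses it more than twice, yields a failed estimate with a flag
(`no_transit` / `multi_transit`) — deliberately mirroring how such
calculations fail on real tracks rather than guessing among crossings.

When samples carry a positional spread, an ensemble of 200 seeded perturbed
paths is evaluated and the 0.50 quantile of their crossing times reported.
Ensemble perturbations are AR(1)-correlated along the track (lag-1
correlation 0.9) because geolocation error persists across days — shading
and calibration biases do not redraw independently each day. Independent
daily perturbations would make nearly every draw fail the crossing-count
rule. This ensemble is an analogue of, not a replica of, posterior crossing
distributions from a particle filter.

Derived quantities and exclusion rules:

* duration = days from the 30% to the 70% crossing, floored at one day;
  speed = great-circle distance / duration;
* estimates of movements within 7 days of an equinox along routes within 15°
  of due north or south are discarded (latitude is unresolvable there);
  equinox dates are fixed at 20 March and 22 September (UTC);
* if a tag stopped within 21 days of the spring equinox — on either side,
  since "within three weeks" is directionally ambiguous — positions after
  1 January of that winter are dropped and flagged;
* birds tracked in multiple years contribute one uniformly chosen track
  (seeded) to the timing models.

Timing contrasts come from ordinary least squares with a phenotype factor
and nuisance covariates (breeding latitude and longitude, year; sex only in
the NW-vs-SW comparison, the divide comparisons being all-male). Backward
elimination removes, one at a time, the covariate with the largest F-test
p-value above 0.10 and refits; the phenotype term is never eliminated. The
elimination order (largest p first) is our choice; only the 0.10 rule is
inherited. Contrasts (SW−SE, S−mean(SW, SE), NW−SW) are built with emmeans
on the final model, with the final model's residual degrees of freedom.
Right-skewed responses (duration, speed) are log-transformed and their
contrasts also reported as ratios.

# Assortative-mating simulation

Each replicate draws phenotype counts for 41 birds from a multinomial with
the configured relative abundances, then an arrival date per bird from its
phenotype's model, then one *directed* pairing per focal bird: the mate is
uniform over all other birds present within 5 days of the focal arrival
(timing-dependent) or over all other birds (timing-independent). The output
is the fraction of pairings where focal and mate are both intermediate (S).
Conventions fixed here:

* Directed pairings (each bird is focal once) rather than unordered pairs —
  "for each individual, select a random mate" implies direction.
* Phenotype shares may sum to less than 1; the remainder becomes an implicit
  `other` phenotype that never counts as S. The divide shares
  53.7/26.8/17.1% leave 2.4% — the odd NW bird — and renormalising instead
  would distort the timing-independent null, which is analytically
  \(p_S^2 = 0.537^2 \approx 28.8\%\) for directed pairings
  (\(E[n_S(n_S-1)]/(N(N-1)) = p_S^2\) under the multinomial).
* If a focal bird's presence window contains no other bird (possible only
  for the earliest arrival), it pairs with the earliest-arriving other bird.
* Default arrival models are Gaussian with the intermediate phenotype
  8.9 days earlier than SW/SE and common SD 6 days — the study's fitted
  density curves are unpublished, so the timing-dependent assortment level
  is checked only qualitatively (it must rise above the timing-independent
  null), not against a fixed figure. Empirical arrival samples can be used
  instead via a Gaussian KDE with Silverman's bandwidth, recorded in the
  model object.

# Ringing-recovery filter

Recoveries qualify as directed southward movements from the breeding region
when: the first encounter lies in the box 8–20° E, 46.6–48.7° N between
15 May and 15 August (month-day comparison, any year); the re-encounter
falls between 1 October and 1 May (wrapping the year end); and the movement
is 100–270° (rhumb bearing, boundaries inclusive, consistent with the
phenotyping convention) over at least 500 km (great-circle). Every failed
criterion is named per record, and the audit conserves counts. Rings with
several re-encounters are evaluated row by row and retained if any row
passes.

# The synthetic-data generator

The generator exists so that every stage is testable without any field
download; its defaults *are* the study conditions: cline centre 14.0° E,
width 0.36° longitude (≈ 27 km at 47.6° N), asymptotes 245°/150°, individual
direction SD 20°; divide phenotype shares 53.7/26.8/17.1%; spring arrival of
S birds 8.9 d and NW birds 9.8 d earlier than SW/SE (SD 6 d), S spring
migration start 14.6 d earlier (SD 7 d); track noise 0.5° SD in longitude
and 1.5° in latitude, the latter tripled within 7 days of an equinox — the
geolocation "equinox problem" in caricature (the ×3 factor is an invented,
documented stand-in). Position noise is AR(1)-correlated along the track
(lag-1 correlation 0.6) because geolocation error is persistent. Breeding
longitudes are sampled half uniformly over 12–16° E and half concentrated
near the cline centre, emulating dense sampling of the divide; migration
distances are drawn per provisional phenotype (SW 1800 ± 250 km, S
1300 ± 250, SE 1900 ± 250, NW 1100 ± 200 — field-plausible round numbers);
travel speed is Normal(150, 30) km/day floored at 60, departure around
12 September (SD 5 d), with stationary pre- and post-migration segments.
Every generator is a pure function of (configuration, seed), and
ground-truth columns (true crossing dates, generating shifts, expected
filter verdicts) ride along for recovery testing.

What the generator does **not** emulate: route curvature (tracks follow the
great circle), stopovers, shading outliers, tag failure, sex differences,
and any covariance between direction and timing. Passing tests therefore
demonstrate that the estimators recover what they claim under the assumed
error structure — not that real geolocator data meet that structure.

# Numerical choices and problem sizes

* Earth constants: R = 6371.0088 km, hence 111.19493 km per degree of arc.
* Cline optimisation: 5 starts, L-BFGS-B, up to 500 iterations; profiles on
  60-point grids; support-interval endpoints by linear interpolation, open
  ends flagged via the `bounded` attribute.
* The recovery experiments used in the tests and the acceptance script run
  at desk scale: 100 simulated transects (40 groups × 4 birds) for the
  cline, 200 cohorts per timing contrast, 1000 mating replicates — sizes at
  which every Monte-Carlo mean sits well inside the tolerances asserted.
* Seeds are explicit arguments everywhere; identical seeds give
  byte-identical CSV outputs (doubles are written with 17 significant
  digits so ground truth round-trips exactly).

# Known limitations

* Directions enter the cline likelihood as linear degrees; a cline spanning
  0/360° would need a circular treatment.
* At the generator's default track-noise level (1.5° latitude SD ≈ 167 km,
  about 1.1 days of travel at 150 km/day), threshold-crossing estimates
  carry an irreducible error of roughly a day: the median absolute error is
  below one day, but no estimator can put 90% of estimates within a day of
  truth under that noise, and a substantial fraction of estimates fail the
  crossing-count rule outright — as threshold timing does on real tracks.
  Precision statements in the tests are therefore split between the
  noiseless regime (exact recovery) and the default-noise regime (median
  error about a day).
* The timing-dependent assortment percentage depends on the shape of the
  arrival-date distributions; with unpublished originals, only its ordering
  against the timing-independent null is a stable target.
* hzar-style MCMC, cline model selection, and stable-isotope comparison
  clines are out of scope.
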
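---
title: "Methods: reproductive allocation, shoot demography and phenology in ascoalloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reproductive allocation, shoot demography and phenology in ascoalloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascoalloc)
```

## The measurement model

*Ascophyllum nodosum* is a long-lived, modular fucoid: a primary shoot grows
apically, laying down one air bladder and one internode per year, and its
tips divide dichotomously. The bladder sequence therefore dates every
segment of the axis. ascoalloc adopts the convention that age 0 is the
current-season, incompletely formed apical segment and age 1 ("S1") is the
newest complete segment; the youngest bladder (b0) subtends the forming
segment and the second-youngest (b1) sits at the base of S1.

Annual production splits into a vegetative and a reproductive term:

* annual vegetative growth, `annV = mean(S1 dry mass) * n`, where the tip
  number `n` is the mean of the b0 and b1 counts. b1 misses tips formed in
  the current season (an underestimate); b0 counts tips that have not yet
  completed a segment (an overestimate); their mean is the working
  compromise, and `tip_count()` exposes all three choices so the bracketing
  can be examined.
* turnover rate `annV / V`, the fraction of standing vegetative shoot
  biomass `V` renewed per year;
* reproductive effort `RE = R / V`, with `R` the whole-shoot receptacle dry
  mass at the reproduction peak (receptacles are shed annually, so a single
  peak sampling captures the year's reproductive output);
* annual reproductive allocation `annRA = R / (R + annV)`, the fraction of
  *annual* production invested in reproduction.

The identity `annRA = RE / (RE + turnover)` follows algebraically and is
enforced to machine precision by the implementation; it is also one of the
package's property tests. annRA is invariant to rescaling all masses by a
common factor, increases in `R` and decreases in `annV`.

Carbon conversion multiplies each term by its tissue carbon fraction;
receptacle tissue is carbon-poorer than vegetative tissue, so C-unit annRA
sits below dry-mass annRA. Areal fluxes multiply standing biomass
(g DW m^-2) by per-shoot turnover and RE and the respective carbon
fractions; means and standard errors are taken across shoots, consistent
with shoot-level replication.

Two reporting conventions deserve note:

* `mean_s1_mass` is a *site-level* mean (apical segments are sampled from
  20-30 individuals per site), applied to every shoot. Site means of
  turnover and annRA therefore carry a shared error component from that one
  mean, which the per-shoot spread does not show.
* Broken shoots (b0 < b1 possible) are excluded from tip-count based
  quantities but keep RE, which needs only measured R and V.

## Within-shoot receptacle formation

Receptacle counts per segment climb from the apex to a peak and decline
toward the shoot origin. `fit_count_age()` models counts as negative
binomial with a log link and quadratic age trend; the peak age is
`-beta1 / (2 beta2)` when the curvature is negative. Repeated measures along
one axis are handled by a shoot-level random intercept
(`method = "NB-with-shoot-intercepts"`, via glmmTMB). Random slopes are
deliberately not fitted: at the realistic replication of 10-14 shoots per
site a random-slope negative-binomial fit is fragile, and the questions of
interest — concavity and peak location — are answered by the intercept-only
model. A pooled fit (`method = "pooled-NB"`, via MASS) is the fast default
for large simulations. Segments older than 12 years are excluded from the
count table, since few shoots exceed that age.

Receptacle size declines roughly linearly with segment age;
`fit_size_age()` is plain OLS on the site-level mean mass per age
(receptacles are pooled per age before weighing, so there is one observation
per age). `cumulative_half_age()` reports the segment age by which half of
all receptacles (counting from the apex) are produced; ties resolve to the
first age reaching the 50% threshold, which makes the statistic
deterministic and matches the "up to age a" reading.

## Phenology convention

Monthly reports of the reproduction peak are converted to approximate Julian
days by assigning the 15th of the month, on a 366-day (leap) calendar —
the calendar choice is forced by the published conversions (July to 197 and
mid/late August to 228 only hold with a 29-day February), while February to
46 and November to -46 are calendar-invariant. Under the default
`autumn-negative` policy, October-December map to day-of-year minus 366:
southern-edge autumn peaks then sit below the late-winter peaks of the
central range and the latitude-timing relation stays monotone instead of
wrapping at New Year. The cutoff at October is configurable
(`wrap_policy = "none"` disables wrapping).

## Meta-regression

`assemble_meta_table()` reduces literature and field records to one point
per region: replicate populations sharing a region tag are averaged
(`n_populations` keeps the count), records reporting only RE are excluded
from the annRA response (RE and annRA are not comparable), and peak months
are converted to Julian days. The same region supplied by two different
sources is rejected rather than silently averaged. The four headline
regressions — annRA and peak Julian day against latitude and mean SST — are
separate univariate OLS fits because latitude and SST are strongly
collinear (`collinearity()` is the screen); each reports slope, adjusted
R-squared `1-(1-R^2)(n-1)/(n-2)`, the two-sided slope test and a
Shapiro-Wilk residual diagnostic. A conservative alpha of 0.01 is the
recommended reading threshold but is not enforced, and no multiple-testing
correction is applied.

The packaged `meta_records.csv` carries the printed regional annRA values;
with the RE-only New England record excluded this gives the canonical
9-point annRA regression. The published 11-point layout needs the three
Nova Scotia regional means, which were never printed individually; the
second packaged table (`meta_records_ns3_synthetic.csv`) splits Nova Scotia
into its three regional groups with synthetic per-population values whose
mean reproduces the printed 0.56, and exists to exercise the grouping rule.
Its adjusted R-squared should not be compared against the published
11-point value. Note also that two of the published tables disagree on
which Disko Bay site sits at 69°24' N; the fixtures follow the site
description (Qeqertarsuaq at 69°24'), and the discrepancy is recorded here
rather than silently resolved. SST retrieval is out of scope: `sst_mean_C`
is an input column (the packaged tables leave it `NA`), and any ocean-layer
backend can fill it upstream.

## The synthetic shoot-population generator

Field data of this kind are not freely redistributable, so every
downstream stage is exercised against a generator that reproduces the
statistical structure the analysis assumes:

* **Tips.** Each tip splits independently each year with probability
  `branch_prob`; b0/b1 are the final two tip counts. The expected ratio
  b0/b1 is `1 + branch_prob`.
* **Counts.** Receptacle counts per segment are negative binomial
  (`nb_dispersion` = size k; variance exceeds the mean for finite k) around
  `exp(beta0 + beta1 age + beta2 age^2 + u)`, with `beta2 < 0` enforced and
  a shoot-level normal random intercept (optionally slope) `u`. Ages below
  `first_reproductive_age` are barren: 2 at the northern range edge, 1
  further south. Lateral segments of age a (there are `tips(A - a)` of
  them) draw their aggregate count from the same model, so whole-shoot `R`
  and the primary-axis count table stay consistent.
* **Masses.** Segment dry masses are lognormal (parameterized by
  natural-scale mean and SD at age 1) modulated by a multiplicative age
  profile; mean receptacle mass declines linearly with age with normal
  noise, floored at 0.001 g because masses are strictly positive.
  `k = Inf` and zero SDs collapse the generator to a deterministic limit
  used in regression tests.
* **Pooling.** The site-level receptacle-mass table is the count-weighted
  mean of realized masses per age: pooling is a measurement operation
  applied to generated receptacles, not a separate random draw.

### Profile calibration

`default_profiles()` ships four parameterizations anchored to the observed
site means across the distribution range: RE 0.14, 0.11, 0.41, 0.73 and
turnover 0.24, 0.22, 0.31, 0.67 (Qeqertarsuaq-, Kronprinsen-, Kobbefjord-
and Hirsholmene-like, spanning the species' reported range of both
metrics). Receptacle size lines use the reported site regressions (e.g.
intercept 0.023 g, slope -0.0011 g yr^-1 for the Kronprinsen-like profile);
maximum ages are 12 years for the Greenland-like profiles and 5 for the
temperate one; branching probabilities (0.28-0.50) give realistic tip
numbers. Standing biomasses use the published site values, and carbon
fractions are synthetic anchors back-derived from the published per-area
carbon fluxes — the profile family is a stylized stand-in, not a
reconstruction of the raw data.

Calibration is moment matching on the estimators actually used, with a
fixed internal seed so it is deterministic:

1. the geometric decay rate of the segment-mass age profile is solved
   (uniroot) so the pilot mean turnover hits its target — turnover depends
   only on the mass profile and tip process, and common random numbers make
   the pilot objective smooth;
2. the count intercept `beta0` is then solved so the pilot mean RE hits its
   target; RE is linear in `exp(beta0)` once count noise is integrated out
   conditionally on tips, random effects and masses, so one correction is
   exact up to pilot error (pilot n = 8000-20000).

Pure expectation-ratio matching (with the usual `exp(sigma^2/2)` lognormal
inflation) is used as the starting point but is not sufficient on its own:
the site estimators are means of per-shoot *ratios*, which carry small
Jensen-gap biases relative to ratios of expectations.

The annRA target of a profile is the calibrated expectation of the
site-mean shoot annRA — *not* `RE*/(RE* + turnover*)`. Under shoot-level
heterogeneity the mean of per-shoot ratios sits well below the identity
evaluated at the site means (for the Kobbefjord-like profile, roughly 0.51
versus 0.57), a distinction worth remembering when comparing site-mean
tables across studies that aggregate differently.

### What the generator does and does not emulate

It reproduces: concave log-linear count-age structure with overdispersion
and shoot heterogeneity, barren young segments, declining receptacle size,
b0 >= b1 tip demography, lognormal segment masses, and site means spanning
the observed RE and turnover ranges. It does not emulate: cohort (year)
effects shared across shoots — so pooled size-age data are much less
scattered than published site fits (R-squared 0.31-0.84), and a shared
year-effect term was considered and rejected as outside the generator's
specified structure; within-shoot serial correlation beyond the random
intercept; broken shoots and partial mortality; or any seasonality within
the year. Passing recovery tests on generated data therefore demonstrates
estimator correctness under the assumed structure, not robustness to every
feature of real field data.

## Numerical and testing choices

* Receptacle-mass floor 0.001 g; mass-model lines are kept positive over
  the profile age ranges so the floor is inactive in calibration.
* Every stochastic operation takes an explicit seed (`simulate_site()` via
  `params$seed`, `simulate_shoot()` via its `seed` argument); reruns are
  bit-identical, which the CLI inherits.
* Recovery tests simulate 500-shoot sites per profile (roughly 40 times the
  field replication, chosen to separate calibration error from sampling
  noise) and compare site means against targets at twice the standard error
  of the estimator. For turnover and annRA that SE includes, by the delta
  method, the shared contribution of the site-mean S1 mass; the plain
  sd/sqrt(n) of per-shoot values understates the sampling error of those
  means because all shoots share the one S1 mean.
* Count-model shape recovery uses 100 replicates of 200-shoot sites with
  the pooled NB fit; size-slope CI calibration uses 100 replicates of
  40-shoot sites with a near-flat count curve so the per-age pools are
  balanced (strongly unbalanced pools make plain OLS intervals undercover —
  a property of OLS on heteroscedastic means, measured at about 89%
  coverage in that regime, not an implementation defect).
* OLS results are cross-checked against an independent numerical
  least-squares minimizer to 6 significant figures.

## Limitations

The hierarchical count fit defaults to random intercepts; users with many
shoots per site can fit richer structures outside the package. The
meta-table treats each region as one exchangeable point and ignores
within-region variance (the published analyses do the same). The areal
upscaling assumes the sampled shoots are representative of the standing
biomass and that biomass estimates are contemporaneous with the allocation
sampling; both assumptions are routinely violated in field campaigns and
should be kept in mind when interpreting g C m^-2 yr^-1 outputs.
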
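# ascoalloc

Quantitative tools for **reproductive allocation and phenology of the
intertidal macroalga *Ascophyllum nodosum*** — from shoot-segment field
records to allocation statistics, carbon fluxes per area, and latitudinal
meta-regressions. The package is aimed at marine ecologists working with
fucoid shoot demography: the annual bladder sequence along a primary shoot
dates every segment, so a single destructive sampling yields an
age-structured record of growth and receptacle formation.

## The statistics at the core

For a shoot with whole-shoot vegetative dry mass *V*, receptacle dry mass
*R* at the reproduction peak, site-mean S1 (newest complete segment) dry
mass, and tip number *n* = (b0 + b1)/2 from the two youngest bladder counts:

* annual vegetative growth: **annV = mean S1 DW × n**
* turnover rate: **annV / V** (yr⁻¹)
* reproductive effort: **RE = R / V**
* annual reproductive allocation: **annRA = R / (R + annV)**, with the
  algebraic identity annRA = RE / (RE + turnover)

Carbon conversion and areal upscaling multiply these by tissue C fractions
and standing biomass (g DW m⁻²). Within shoots, receptacle counts per
segment follow a concave quadratic log-mean in segment age, fitted as a
negative-binomial regression with optional shoot-level random intercepts;
receptacle size declines linearly with age. Reproduction-peak months are
converted to approximate Julian days (15th of the month, 366-day calendar,
autumn months mapped negative), and annRA and peak timing are regressed on
latitude and mean SST across the distribution range.

A calibrated synthetic shoot-population generator (`sim_params()`,
`simulate_site()`, `default_profiles()`) reproduces the statistical
structure the analysis assumes, with four site profiles spanning the
observed RE (0.11–0.73) and turnover (0.22–0.67) ranges, so every stage is
testable without access to restricted field data.

## Worked example

```r
library(ascoalloc)

params <- default_profiles()[["kobbefjord-like"]]
params$n_shoots <- 12L; params$seed <- 2023L
d <- simulate_site(params)

site_summary(d)
#> <asco_site_summary> 12 shoots
#>   metric    mean     se     n
#> 1 annV     2.26  0.347     12
#> 2 turnover 0.316 0.0132    12
#> 3 RE       0.391 0.0899    12
#> 4 annRA    0.507 0.0345    12
#> 5 annRA_C  0.425 0.0350    12

areal_production(d$site, site_summary(d))
#> <asco_areal_production> g C m-2 yr-1
#>   component     mean    se
#> 1 vegetative    905.  37.6
#> 2 reproductive  789. 181.
#> 3 total        1694. 203.

fit_count_age(counts_by_age(d), method = "NB-with-shoot-intercepts")
#> <asco_count_fit> NB-with-shoot-intercepts, n=156 obs
#>   log lambda = -1.317 +0.664 age -0.0711 age^2   (k = 0.545)
#>   peak age: 4.67 yr
```

Twelve simulated shoots of the Kobbefjord-like profile allocate about half
of their annual production to reproduction (annRA 0.51 ± 0.03; the C-unit
value is lower because receptacle tissue is carbon-poorer), renew ~32% of
their vegetative biomass per year, and upscale to ~1.7 kg C m⁻² yr⁻¹ of
which receptacles — all shed after gamete release — export ~0.8 kg. The
count model recovers the concave age trend with its receptacle-formation
peak near segment age 4–5.

Phenology and the cross-study regression:

```r
month_to_julian_day(c(2, 7, 8, 11))
#> [1]  46 197 228 -46

meta <- assemble_meta_table(read_meta_records(asco_example("meta_records.csv")))
run_headline_regressions(meta)$annRA_latitude
#> <asco_ols> y = 1.07 -0.00985 x;  adj R2 = 0.73, p = 0.0022, n = 9
```

Across nine literature and field regions, annRA declines by about one
percentage point per degree of latitude northward.

A small CLI wraps the same functions
(`system.file("cli", "ascoalloc.R", package = "ascoalloc")`), with
subcommands `simulate`, `allocate`, `shootfit`, `phenology` and `meta`;
every run writes a machine-readable `summary.json` plus `run.log` and is
bit-identical under a fixed seed.

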
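# linkenhance

Enhanced reporting of deaths from linked administrative health records.

## The problem

Death registrations under-report membership of some population groups —
the motivating case is Aboriginal and Torres Strait Islander peoples in
Australian registration data — so death counts, median age at death and
standardised mortality ratios computed from registrations alone are
biased. When death records are linked to a person's hospital, emergency
department, perinatal and birth-registration records, each linked record
carries an independently collected report of the person's status, and
that evidence can be used to *enhance* the death data.

`linkenhance` is aimed at epidemiologists and health-statistics analysts
who want to implement, stress-test or teach this enhancement approach.
It provides:

* **Unit derivation** — linked records become independent "units of
  information": transfer-linked hospital episodes collapse into stays
  (one stay = one unit), and parent status is inherited onto infant
  birth records.
* **Three reporting methods** — with `n` countable units of which `k`
  report membership:
  * *as reported*: the death registration flag alone;
  * *at least one report*: any unit reporting membership;
  * *weight-of-evidence algorithm*: `k ≥ 2` when `n ≥ 3`, `k ≥ 1` when
    `n ≤ 2` (plus a proportion-threshold variant family).
* **Indicators** — stratified counts with percent increases, median age
  at death, and indirect-standardisation SMRs (×100) with exact gamma
  confidence intervals (half-χ² quantiles at `2d` and `2(d+1)` df).
* **Sensitivity analysis** — closed-form and simulated impact of
  per-record false-positive reports; the arithmetic showing an excess of
  Δ deaths across N linked records needs only `10⁴·Δ/N` false reports
  per 10,000 records.
* **A synthetic linked-data generator** — real linked registry extracts
  are confidential, so the package ships a generator emulating
  differential reporting sensitivity (death record 0.76,
  admitted-patient 0.88, perinatal 0.68), age/cause-dependent
  hospitalisation, transfer-linked episodes, and linkage errors
  (4/1000 false links, 5/1000 missed links).

## Worked example

```r
library(linkenhance)

cfg <- generator_config(n_deaths = 5000, seed = 42)
co  <- generate_cohort(cfg)              # deaths, linked records, truth
res <- enhance_dataset(co$deaths, co$linked)
method_counts(res)
#>  as_reported    algorithm at_least_one
#>           89          110          110

tabs <- build_tables(co$deaths, res)
tabs$counts[tabs$counts$axis %in% c("cause", "total"), ]
#>   axis        stratum as_reported algorithm algorithm_increase at_least_one at_least_one_increase
#>  cause         cancer          18        25               38.9           25                  38.9
#>  cause cardiovascular          26        31               19.2           31                  19.2
#>  cause       external           8        10               25.0           10                  25.0
#>  total          Total          89       110               23.6          110                  23.6
```

The cohort contains 113 true members; the registration data alone report
89 of them, and enhancement recovers 110 — a 23.6% increase. With no
false-positive reports the two enhancement methods agree. They separate
exactly where it matters: under a small per-record false-positive rate
the "at least one report" count inflates roughly linearly while the
weight-of-evidence algorithm, which needs two concordant reports, barely
moves:

```r
sw <- sensitivity_sweep(cfg, fp_grid = c(0, 2e-3, 1e-2), n_seeds = 3)
summarise_sweep(sw)
#>  fp_rate as_reported_mean algorithm_mean at_least_one_mean
#>    0.000            73.67          96.67              98.0
#>    0.002            73.67         102.33             134.3
#>    0.010            73.67         124.00             295.7

required_misclassification_rate(128, 648746)
#> [1] 1.97   # false reports per 10,000 linked records that would explain
#>            # a 128-death gap between the two methods
```

SMRs with exact intervals:

```r
smr_with_ci(observed = 110, expected = 45)
#>  observed expected      smr   ci_low  ci_high alpha
#>       110       45 244.4444 200.9036 294.6217  0.05
```

A command-line interface mirrors the pipeline
(`generate`, `enhance`, `indicators`, `sensitivity`):

```sh
Rscript -e 'linkenhance::linkenhance_cli()' generate --seed 42 --out cohort/
Rscript -e 'linkenhance::linkenhance_cli()' enhance \
    --deaths cohort/deaths.csv --linked cohort/linked.csv --out enhanced.csv
```

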
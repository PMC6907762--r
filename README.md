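# dutyhours

Objective duty-hour monitoring for residency programs, from EHR audit
logs. Trainee self-report systems are onerous and biased; the timestamps
trainees leave in the electronic health record are neither. `dutyhours`
turns a raw access-log export into inferred work shifts, evaluates
duty-hour rules over both EHR-defined and self-reported shifts, and
quantifies systematic under-reporting at the resident-block level. A fully
seeded simulator generates schedules, event streams and biased
self-reports with known ground truth, so the entire pipeline is testable
without any protected data.

## Method

**Shift inference.** For each trainee the on-site event stream is
sessionized: a shift is a maximal run of events whose inter-event gaps are
all strictly below a threshold *g* (default 300 min), with start/end at
the run's first/last event. Candidates closer than 60 min are merged, then
candidates shorter than 60 min are dropped. Endpoints are observed events,
so inferred duty time under-estimates but never over-estimates.

**Rule engine.** A `DURATION` violation is a shift strictly exceeding the
role cap (16 h for interns, 28 h = 24+4 h for seniors), with magnitude the
excess in minutes. An `INTERVAL` violation is rest strictly below the
requirement between adjacent shifts (8 h after shifts ≤ 16 h, 14 h after
longer shifts), attributed to the later shift.

**Comparison.** Violations are tallied per resident-block (trainee x
rotation x 4-week block). Blocks with zero self-reported shifts are
excluded from paired analyses. Each eligible block is classified by
sign(SRV − EDV); role contrasts use ANOVA + Tukey HSD; the source effect
is estimated by OLS on the long form,

    total_violations ~ source_SRV + role_SR_FLC + role_SR_SUPRV

where a negative `source_SRV` coefficient is the under-reporting effect in
violations per block.

## Worked example

```r
library(dutyhours)

sim <- simulate_study(n_trainees = 60, seed = 1)          # one academic year
eds <- infer_all_shifts(filter_onsite(sim$events, sim$workstations))
res <- compare_cohort(eds, sim$self_reports, sim$roster, sim$calendar)

res$role_edv$summary
#> # A tibble: 3 × 4
#>   role     n_blocks  mean    sem
#>   <fct>       <int> <dbl>  <dbl>
#> 1 JR_FLC        325 0.609 0.0431
#> 2 SR_FLC        328 2.16  0.0929
#> 3 SR_SUPRV      127 1.34  0.109
res$excess
#> # A tibble: 1 × 4
#>       n median    q1    q3
#>   <int>  <dbl> <dbl> <dbl>
#> 1   970   34.0  17.5  69.8
res$paired$summary
#> # A tibble: 1 × 7
#>   n_blocks n_under n_over n_equal pct_under pct_over pct_equal
#>      <int>   <int>  <int>   <int>     <dbl>    <dbl>     <dbl>
#> 1      586     192      0     394      32.8        0      67.2
res$model$coefficients[2, ]
#> # A tibble: 1 × 5
#>   term       estimate std_error t_value  p_value
#>   <chr>         <dbl>     <dbl>   <dbl>    <dbl>
#> 1 source_SRV   -0.478    0.0674   -7.09 2.37e-12
```

Reading: junior front-line clinicians average 0.6 EHR-defined violations
per block against 2.2 for senior front-line; over-cap shifts run a median
34 min past the limit; 32.8% of eligible blocks self-reported fewer
violations than the EHR shows; and adjusted for role, self-reports carry
0.48 ± 0.07 fewer violations per block than the EHR-defined count — the
under-reporting effect.

The same computation, stage by stage with intermediate tables written
under `results/`, is in the `analysis/` scripts:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_infer_shifts.R
Rscript analysis/03_detect_violations.R
Rscript analysis/04_compare_cohort.R
```

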
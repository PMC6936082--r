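# idenhance

Enhancement of Aboriginal and Torres Strait Islander status identification
across person-linked health datasets, and quantification of its impact on
cancer case counts and age-standardised incidence rates.

## The problem

Aboriginal and Torres Strait Islander people are under-recorded in routinely
collected Australian health data, so absolute measures of cancer burden
computed from a single registry status field are biased downwards. When a
cancer registry is person-linked to hospital admission, emergency-department
and cause-of-death collections, each person carries several independent
observations of their Indigenous status. `idenhance` combines those
observations into an enhanced person-level status using four standard
algorithms, and measures what the enhancement does to case counts and to
directly age-standardised incidence rates (ASRs).

The package is aimed at cancer-registry and population-health analysts who
work with linked administrative data, and at methodologists studying
misclassification of group membership across linked sources.

## Methods implemented

Every record with a known (non-unknown) status from the admissions (APDC),
emergency (EDDC) or death (COD URF) collections is a *unit of information*.
Two rules take precedence over everything: a person recorded as Aboriginal
on the registry (NSWCR) or on a death certificate is accepted as Aboriginal,
and enhancement only ever changes persons recorded as non-Aboriginal or
unknown (never the reverse). For eligible persons:

| Method | Classified Aboriginal when |
|---|---|
| ever-reported | any unit records the person as Aboriginal |
| most-recent-record | the latest-dated unit is Aboriginal (ties resolve Aboriginal if any tied unit is) |
| weight-of-evidence | >= 2 of >= 3 units are Aboriginal, or >= 1 of 1-2 units |
| multi-stage-median | weight-of-evidence applied within each source dataset, then across the per-dataset results |

Rates are directly standardised to the 2001 Australian standard population
over 18 five-year age bands: ASR = &Sigma;<sub>b</sub> w<sub>b</sub>
d<sub>b</sub> / n<sub>b</sub> &times; 100,000, with 95% confidence
intervals from a gamma approximation to the weighted Poisson sum (the
Dobson-type interval conventional in registry reporting; exact at zero
counts). Enhancement changes numerators only; Aboriginal population
denominators are held fixed across methods.

Because the real linked datasets are restricted, the package includes a
seeded synthetic cohort generator (`simulate_cohort()`) with a latent true
status per person and per-source sensitivity / false-positive / unknown-rate
recording processes, so the whole pipeline is testable and recovery of the
latent status can be scored (`evaluate_recovery()`).

## Worked example

```r
library(idenhance)
co <- simulate_cohort(sim_config(n_persons = 10000, seed = 42))
e  <- enhance(co$records, persons = co$cases$person_id)
e
#> Indigenous status enhancement: 10000 persons, methods: ever, most_recent, weight_of_evidence, multi_stage_median
#> Unit sources: APDC, EDDC, COD_URF
#> Base (registry) Aboriginal: 167 (1.7%)
#>   ever                 Aboriginal: 547 (+380 changed)
#>   most_recent          Aboriginal: 346 (+179 changed)
#>   weight_of_evidence   Aboriginal: 346 (+179 changed)
#>   multi_stage_median   Aboriginal: 391 (+224 changed)
```

Of 10,000 simulated cancer cases, 167 (1.7%) are recorded Aboriginal on the
registry variable; the ever-reported rule lifts that to 547 and the
weight-of-evidence rule to 346. Counts and relative increases by stratum:

```r
build_count_table(co$cases, e, "sex")[, c("stratum", "total", "base_n",
                                          "ever_n", "ever_increase",
                                          "weight_of_evidence_n",
                                          "weight_of_evidence_increase")]
#>   stratum total base_n ever_n ever_increase weight_of_evidence_n weight_of_evidence_increase
#> 1  female  5000     88    299         239.8                  185                       110.2
#> 2    male  5000     79    248         213.9                  161                       103.8
```

Age-standardised rates (per 100,000, 95% gamma CI) for all cancers,
persons — enhancement roughly doubles the Aboriginal ASR here:

```r
rt <- build_rate_table(co$cases, e, co$population,
                       sites = data.frame(label = "all_cancers",
                                          codes = NA, sex = "both"))
round(rt[rt$scope == "persons",
         c("non_aboriginal_asr", "base_asr", "base_ci_low", "base_ci_high",
           "weight_of_evidence_asr", "weight_of_evidence_increase")], 1)
#>   non_aboriginal_asr base_asr base_ci_low base_ci_high weight_of_evidence_asr weight_of_evidence_increase
#> 1              204.7    128.3        88.6        192.9                    254                          98
```

Because the cohort is simulated, recovery of the latent true status can be
scored directly:

```r
evaluate_recovery(co$truth, e)[, 1:5]
#>               method sensitivity specificity   ppv prevalence_enhanced
#> 1               ever       0.988       0.976 0.581              0.0547
#> 2        most_recent       0.925       0.995 0.861              0.0346
#> 3 weight_of_evidence       0.984       0.997 0.916              0.0346
#> 4 multi_stage_median       0.984       0.992 0.811              0.0391
```

The ever-reported rule is the most sensitive but least precise;
weight-of-evidence keeps nearly the same sensitivity at much higher
positive predictive value — the trade-off that makes it attractive for
population-level reporting. `run_pipeline()` drives
simulate → enhance → tables end to end and writes CSV outputs plus a run
manifest.

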
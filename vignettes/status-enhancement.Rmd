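---
title: "Enhancing Indigenous status across linked health datasets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing Indigenous status across linked health datasets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idenhance)
```

## The estimation problem

A statutory cancer registry records each person's Aboriginal and Torres
Strait Islander status, but the field is incomplete and misclassified:
status is missing when the registry only receives a pathology notification,
and people may not be identified at the point of care. Person-level linkage
to hospital admissions (APDC), emergency presentations (EDDC) and death
registrations (COD URF) supplies additional, independently collected status
observations per person. The quantity of interest is each person's binary
status (Aboriginal vs non-Aboriginal) for reporting case counts and
incidence rates; the three-valued recorded field (Aboriginal,
non-Aboriginal, unknown) is the observation.

`idenhance` treats this as an attribute-resolution problem: combine a
person's status observations into one enhanced status under a declared
rule, then propagate that status into count and rate tables.

## Units of information and the four rules

A *unit of information* is a single record with a known (non-unknown)
status from one of the contributing sources. Two conventions are applied
before any rule:

* **Precedence.** A person recorded Aboriginal on the registry, or on any
  death record, is Aboriginal outright. Next-of-kin-reported death
  information is treated as highly reliable, and the registry's own
  positive identification is never overturned.
* **Eligibility.** Only persons recorded non-Aboriginal or unknown can be
  changed, and only towards Aboriginal: the purpose is correcting
  under-recording, not re-adjudicating positive identifications.

For eligible persons, with $n$ units of which $k$ are Aboriginal:

* *ever-reported*: Aboriginal iff $k \ge 1$;
* *most-recent-record*: the status of the latest-dated unit; ties on the
  latest date resolve Aboriginal if any tied unit is Aboriginal;
* *weight-of-evidence*: Aboriginal iff ($n \ge 3$ and $k \ge 2$) or
  ($1 \le n \le 2$ and $k \ge 1$);
* *multi-stage-median*: the weight-of-evidence rule applied within each
  source dataset that has at least one unit, then across the per-dataset
  results, each dataset counting as one unweighted unit.

With no units anywhere a person keeps their base status, with unknown
folded into non-Aboriginal at reporting time. These definitions force a
strict order: the ever-reported Aboriginal set contains every other
method's set, every method's set contains the base registry set, with at
most two units weight-of-evidence coincides with ever-reported, and with a
single contributing dataset multi-stage-median coincides with
weight-of-evidence. The test suite verifies all of these, plus exhaustive
agreement with an independently coded rule evaluator over every unit
multiset of size $\le 6$ across the three sources.

### Design choices where the rules are underdetermined

The rule definitions leave several details open; the package fixes them as
follows.

* **What counts as a unit.** One record with a known status. Per-record
  counting follows the multi-source enhancement literature and makes
  record-level noise meaningful; whether repeated notifications should
  collapse within an admission is not decidable from the rule definitions,
  so the contributing sources are configurable (`unit_sources`).
* **The registry is not a unit.** Its status is the quantity being
  corrected, and a positive registry status already decides the outcome
  through precedence; counting it again would double-weight the variable
  under evaluation.
* **Unknown records and most-recent.** An unknown-status record cannot
  "record the person as Aboriginal", so the most-recent rule uses the most
  recent *known* status.
* **Date ties.** Resolved Aboriginal-if-any-tied-Aboriginal, consistent
  with the positive-identification stance of registry practice. Documented
  and covered by tests; with day-resolution dates ties are rare in real
  data.
* **Zero units.** The weight-of-evidence conditions are silent at $n = 0$;
  the base status is retained.

## Rates

Age-specific rates use cases per person-years within 18 five-year age
bands (0–4 … 85+), person-years being the annual population counts summed
over the diagnosis-year range without mid-year interpolation. The directly
standardised rate is

$$\mathrm{ASR} = \sum_b w_b \frac{d_b}{n_b} \times 100{,}000,$$

with $w_b$ the 2001 Australian standard population weights (packaged as a
CSV; weights renormalise with a warning if a band is absent from the
population table). Each cancer case counts once, and a person's status is
shared across all of their cases. Enhancement changes numerators only: the
Aboriginal population denominator is identical across methods, which
mirrors registry practice and is the source of the numerator–denominator
bias discussed below.

**Confidence intervals.** The level is 95% by default. The reported
interval is the gamma approximation to the weighted Poisson sum
(Dobson-type, with the largest single-case weight entering the upper
limit), the convention in registry reporting and exact at zero counts: a
zero-case stratum yields ASR 0 with a zero lower limit and a positive
upper limit. A normal approximation is available via `ci_method =
"normal"` for comparison. The acceptance suite measures empirical coverage
over 1,000 seeded Poisson replicates at a known true ASR, using a
cancer-like rising rate schedule over a young-skewed population of 250,000
person-years; coverage is required to fall in 93–97%.

**Rounding.** Percentages and rates round half away from zero (the
convention of the SAS-based registry tables), one decimal by default and
zero decimals for abstract-style proportions; base R's `round()`
half-to-even would not reproduce printed registry tables. Relative change
is $100 (e - b) / b$, undefined (flagged, not zero) when $b \le 0$.

## What the simulator emulates

`simulate_cohort()` generates a person-linked cohort from a latent truth:

* a latent binary status per person, Aboriginal with probability
  `prevalence_true` (default 0.03, approximately the NSW Aboriginal
  population share);
* per-source record counts, Poisson with configurable means, truncated to
  at most one record for the registry and the death file (a person has one
  registry status and one death); death records exist only for the
  `death_probability = 0.2` of persons simulated as decedents;
* per-record recorded status: unknown with `unknown_rate`, otherwise
  Aboriginal with `sensitivity` for truly Aboriginal persons and with
  `false_positive_rate` for others;
* record dates uniform within each source's coverage window — July 2001 to
  December 2017 (admissions), January 2005 to December 2017 (emergency),
  January 1985 to December 2015 (deaths) — with diagnoses in 2010–2014;
  only the ordering matters, and only to the most-recent rule;
* one incident cancer case per person with sex, five-year age band (an
  old-skewed registry-like distribution), ICD-10 site, degree of spread,
  remoteness and socio-economic quintile;
* deterministic background denominators: the cohort's expected
  age–sex–group structure scaled by `population_multiplier` (default 100),
  constant across years, so that rates are computable at desk scale.

Default misrecording magnitudes are plausible rather than estimated —
registry sensitivity 0.55 with a mean of 2 (truncated) registry
notifications, so about 13.5% of persons lack a registry record and start
unknown, close to the 13.9% unknown share observed in registry data;
admissions and emergency sensitivities 0.85 and 0.80 with several records
per person; death-record sensitivity 0.90; false-positive rates of a few
per thousand. All are configurable per source.

Draws are independent per record by default, which is exactly what lets
within-person inconsistency — the signal the enhancement rules exploit —
arise. An optional `per_person_consistency` parameter correlates a
person's identification draws across records and sources (0 = independent,
1 = a single shared draw), emulating stable propensity to self-identify.

### What the simulator does not emulate

Real status sequences are time-correlated (identification improves over
calendar time and people change how they identify once, not per record),
under-recording correlates with service-use patterns and cancer prognosis,
and linkage itself has error. None of this is modelled. Two visible
consequences: enhancement under the independent-noise default is *stronger*
than in real linked data, because many independent observations of a truly
Aboriginal person almost surely contain two Aboriginal records — so
simulated relative increases (roughly doubling Aboriginal counts at the
defaults) exceed those observed in practice (tens of per cent); and the
most-recent rule is not guaranteed to be the most conservative method
here, as it is in real data where later records are more accurate, because
under exchangeable record noise its single-record decision carries a
higher false-positive rate than the two-of-many weight-of-evidence rule.
Passing recovery tests on this generator therefore validates the *logic*
of the rules and pipeline, not the real-world magnitude or ranking of
enhancement effects.

## Problem sizes and determinism

All randomness flows from a single integer seed in the configuration, and
the generator restores the caller's random-number state, so identical
configurations are byte-identical on re-run. The validation suite uses
50,000-person cohorts for recovery and calibration checks (about 300,000
records), 20,000-person cohorts for order properties, and exhaustive
enumeration (924 multisets × 2 base statuses) for rule equivalence; the
whole suite runs in well under a minute on one CPU.

## Known limitations

* Person linkage is taken as given via an opaque identifier; linkage error
  is out of scope.
* Denominators are never enhanced: enhancing the numerator while the
  population denominator identifies the group by a different method can
  overstate rates (numerator–denominator bias). The package deliberately
  reproduces this reporting convention rather than correcting it.
* Torres Strait Islander status is not modelled as a separate category.
* The small ICD-10 site lookup covers the reported sites (C50, C18–C20,
  C61, C34, C43, C53) plus a configurable remainder; full clinical
  cancer-group mapping is out of scope.
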
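---
title: "Simulating the Colombian gestation care pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the Colombian gestation care pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestsynth)
```

## Why synthetic obstetric records

Structured, shareable clinical data on pregnancy care are scarce: electronic
records rarely encode gestational start, end and age consistently, access to
primary data is restricted, and pregnant women are under-represented in the
public datasets used to develop clinical software and AI models. A fully
synthetic cohort sidesteps privacy constraints while preserving the *shape*
of real care: longitudinal encounters, coded diagnoses and procedures, and
realistic complication frequencies. `gestsynth` generates such cohorts for
the Colombian antenatal care context and exports them to the OMOP Common
Data Model (CDM v5.4) so they drop into standard observational-research
tooling.

## The model: a clinical state machine

Each woman is simulated by walking a directed graph of typed states:

* **Initial / Simple / Terminal** — control flow only.
* **Delay** — advances the clock by a whole number of gestational weeks
  (fixed, or uniform over an integer range). One week is the model's time
  granularity: the pathway is designed week by week, and no clinical event
  in antenatal care needs finer resolution.
* **Encounter, ConditionOnset, ConditionEnd, Procedure, Observation** —
  append one coded clinical event (SNOMED-CT, CIE-10 or CUPS) to the
  person's log.
* **SetAttribute** — writes a person attribute (e.g. `pregnant`, `preterm`)
  that later `Conditional` transitions can test.
* **Death** — a mortality outcome event.

Transitions are `Direct` (probability 1), `Distributed` (a draw from a
discrete distribution whose probabilities must sum to 1 within $10^{-9}$),
or `Conditional` (attribute predicates evaluated in order, with a mandatory
catch-all final branch so a walk can never dead-end — incoherent clinical
sequences are a known failure mode of hand-authored modules, and the
catch-all rule removes one class of them by construction). Modules are
stored as JSON (schema in `inst/schema/module-schema.json`; the dialect is
self-defined) and `validate_module()` audits every invariant, including
probability mass and unreachable states. A step budget of 10,000 —
two orders of magnitude above the pathway's depth — converts authoring
cycles into errors instead of hangs.

Reproducibility is a contract, not an accident: `simulate_person()` is a
pure function of (module, person, seed), and a cohort master seed $k$
derives person $i$'s streams deterministically from $(k, i)$, so person 42
has the same biography alone or inside any cohort.

## The gestation module

The shipped pathway covers conception (week 0, dated from the last menstrual
period) to the postpartum control at up to week 43. Its inventory: 16
encounter states (10 prenatal controls at weeks 8–32, two ultrasound visits,
an emergency visit, the delivery admission, a postpartum control, and a
pregnancy-loss management visit), 16 distinct condition codes, a
representative procedure set including the guideline vaccinations (tetanus,
influenza, pertussis), one observation (gestational age at birth) and one
maternal-death outcome state.

Complications are *gates*: scheduled Bernoulli decision points anchored to
the trimester where the condition clinically presents —

| gate | week | terminates pregnancy |
|---|---|---|
| ectopic pregnancy | 8 | yes |
| abortion, 1st trimester | 10 | yes |
| abortion, 2nd trimester | 16 | yes |
| hypertensive disorders (PIH, chronic, complication) | 20 | no |
| preeclampsia / eclampsia | 22 / 24 | no |
| gestational diabetes | 26 | no |
| growth restriction, hemorrhagic complications, placenta previa | 28 | no |
| PROM, abruptio placentae | 30 | no |
| preterm birth draw | 32 | no |
| postpartum hemorrhage | after delivery | no |

Gestational length is categorical: the week-32 gate marks a woman preterm
(delivery uniform over weeks 33–36, with the preterm-newborn condition
recorded at delivery) or term (uniform 37–41). The literature consulted for
the pathway gives point prevalences, not a gestational-age distribution, so
a uniform term window is the least-informative choice consistent with the
clinical definitions.

### Calibration: marginals to conditionals

Configuration is stated as *marginal* frequencies — the fraction of the full
cohort with each condition — because that is what surveillance data report.
The machine, however, draws each gate *conditionally* on reaching it.
`conditional_from_marginals()` converts one to the other: with gates in
pathway order and $T(g)$ the terminating gates before $g$,

$$ c_g \;=\; \frac{m_g}{1 - \sum_{t \in T(g)} m_t}. $$

With the default counts over the 10,637-woman reference cohort: the ectopic
gate draws at $218/10637$, first-trimester abortion at $1714/10419$,
second-trimester abortion at $636/8705$, and every later gate among the
$8069$ women reaching delivery (preterm $603/8069$, postpartum hemorrhage
$1443/8069$). Forward-multiplying each conditional by the survivor mass
before its gate returns the marginals exactly; the test suite checks this
against an independent exhaustive enumeration of gate-outcome sequences to
$10^{-12}$.

Design choices worth making explicit:

* **Calibration targets are observed counts**, not literature ranges: only a
  concrete count column determines a unique parameter set. The literature
  ranges instead drive the validation report.
* **Non-terminating complications are independent Bernoulli gates** given
  still being pregnant (or delivered, for postpartum hemorrhage). No
  dependency structure between complications is imposed — in particular
  eclampsia is drawn at its own marginal ($445/10637$), independent of
  preeclampsia. Independence is the minimal assumption when no joint
  frequencies are available, and it means the model reproduces marginals,
  *not* clinically plausible co-occurrence patterns.
* **Placenta previa and abruptio placentae** complete the 16-condition
  inventory but have no reference counts; they default to marginal 0.005
  each and are configurable. **Premature rupture of membranes** defaults to
  marginal 0, so no default cohort ever contains it.
* **Maternal death** is modelled as a gate after postpartum hemorrhage with
  default probability 0: the outcome state exists and is structurally
  reachable, but no default cohort generates a death and the exported CDM
  death table is empty. Raising `p_maternal_death` in
  `build_pregnancy_module()` activates it.

```{r calibration}
g <- conditional_from_marginals(default_gates())
g[g$code %in% c("34801009", "19169002", "367494004"),
  c("code", "display", "marginal", "conditional")]
```

## Demographics

Every person is female — the generator produces pregnancy records only, and
the tests assert the contract. Municipality of residence is drawn
proportional to a DIVIPOLA-coded weight table; the bundled
`municipality-weights-synthetic.csv` is a 30-municipality synthetic stand-in
with plausible relative populations (a real census table is a drop-in CSV).
Age at conception is uniform over 15–49 completed years — the cohort's
age structure is unspecified by the frequency targets, and a uniform draw
over the reproductive age range keeps every age represented without
asserting an age pyramid we have no parameters for. Conception dates are
uniform over a configurable calendar-year window (default 2023).

Department-restricted generation (`filter_department()`, or
`department = "05"` in a run) renormalizes the weights within one
department. For a national run, drawing each person's municipality from the
full table is distributionally identical to first allocating persons to
departments by a multinomial draw on department weights, and keeps the
per-person streams order-independent — so that is the implementation.

## OMOP CDM v5.4 export

`export_cdm()` maps each event log to seven tables: `person`, `location`,
`observation_period`, `visit_occurrence` (one row per Encounter event),
`condition_occurrence` (one per ConditionOnset, linked to the visit active
at onset), `procedure_occurrence`, and `death`. Locations carry the
Colombian political division: municipality code in `city`, department code
in `state`. Concept ids come from a concept-map CSV; the bundled map is a
synthetic vocabulary stand-in (the female gender concept 8532 follows the
CDM convention, and is read from the map, not hard-coded). Unmapped codes
take concept id 0 while the source code and display are always retained in
`*_source_value` — including visit-type detail and the qualitative
observation content, so no clinical information is dropped by the ETL. Rows
are ordered by person id then event order and dates serialize ISO-8601, so
re-exporting the same cohort is byte-identical; `integrity_check()` verifies
referential integrity as data rather than assertions.

## The validation report

`frequency_report()` recomputes, per condition, the distinct-person count,
the percentage of the cohort (rounded half-up to one decimal for
presentation; the raw fraction is kept in `percent_raw`), and the distance
to the literature range under the sign convention *observed minus
reference*: distance to the lower and upper bounds for a range, a single
direct difference for a point estimate. No agreement statistic is attached:
with fixed point estimators and no reported variability, a qualitative
comparison is the honest summary.

## What passing tests do and do not show

The generator reproduces *cohort-level marginal frequencies* under the
study conditions: $N = 10{,}637$, one seed, each condition within four
binomial standard errors of its target. It does not emulate real data's
correlation structure (complications co-occur independently), care-seeking
variability (every term pregnancy follows the same encounter schedule, a
degree of determinism that a real cohort would not show), fetal/newborn
records beyond the preterm code, substance-exposure risk factors, or
maternal mortality (default probability 0). Validation against the
literature is qualitative by design; the reference estimates are
predominantly international, so the synthetic cohort inherits their
imprecision about Colombian epidemiology.

## Problem sizes and numerical choices

The test suite exercises the full reference size $N = 10{,}637$ once
(shared across acceptance checks) and uses cohorts of 200–2,000 for
structural properties; branch-frequency and demographic-sampling checks use
$10^5$ and $5 \times 10^4$ draws with $4\,\mathrm{SE}$ bands and a
$\chi^2$ goodness-of-fit at $\alpha = 0.001$. Distributed probability mass
is checked to $10^{-9}$; the calibration identity to $10^{-12}$; survivor
mass $\le 0$ raises an infeasible-calibration error rather than clamping.
Ties in presentation rounding go half-up, away from banker's rounding, to
match how surveillance tables are printed.
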
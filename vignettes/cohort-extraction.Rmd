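---
title: "Automated cohort extraction from longitudinal primary-care records: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated cohort extraction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehretl)
```

## The problem

Observational research on primary-care databases (THIN- or CPRD-like
structures: practices, registered patients, coded clinical/therapy/measurement
events) spends most of its effort not on analysis but on *extraction*:
turning raw longitudinal tables into one analysable row per study subject,
under a study design — cohort, case–control or cross-sectional — with
reproducible eligibility windows, exposure definitions, matched controls,
outcomes and baseline covariates. Done by hand this is slow, error-prone and
hard to verify. `ehretl` implements extraction as a six-stage
extract–transform–load pipeline in which the design is *data* (a declarative
`study_design()`), every patient removed at any point is counted against a
documented reason, and the whole run is reproducible from one seed.

The six stages are:

1. **Eligibility** — derive per-practice and per-patient observation windows
   from the study period, data-quality key dates, registration, death and
   age limits.
2. **Exposure / case definition** — locate code entities and evaluate the
   exposure combination logic, assigning index dates.
3. **Control pool** — optionally refine patients who failed the exposure
   logic into a potential-control pool with its own logic.
4. **Matching** — randomized without-replacement selection of controls per
   exposed/case under the full criterion set; controls inherit the
   exposed's index date.
5. **Outcomes** — first post-index occurrence of each outcome entity and
   the patient exit date.
6. **Assembly** — baseline-variable extraction, the wide analysable
   dataset, attrition table, audit log and optional AES-256 encryption.

A cross-sectional design runs stages 1, 2 and 6 only: there is no control
selection, matching or outcome determination. Cohort and case–control
designs share the full flow; stages 3–4 run only when controls are
required.

## Calendar conventions

All intervals are **closed** (inclusive at both ends). "Before the patient
end date" is read as *on or before*: a record made on the end date is real
observed data, and one convention has to be fixed and tested. The only
deliberate exception is the stage-1 overlap test between the patient and
practice windows, which uses strict inequalities (`patient_start <
practice_end` and `patient_end > practice_start`), read literally from the
procedure it implements; a patient whose window only touches the practice
window at a single endpoint is rejected.

Ages are completed years. "The date a patient attains age x" is the x-th
anniversary of birth; a Feb-29 anniversary in a non-leap year rolls forward
to Mar-1, so the attainment date is always the first day on which the
patient *is* x years old. Year-precision birth dates are normalised at load
to July 1 of the birth year (configurable to January 1); mid-year is the
expectation-neutral choice for age arithmetic when only the year is
recorded.

Dates in the flat-file database are ISO-8601. Design configuration files
additionally accept DD/MM/YYYY, the format in which study periods are
typically communicated in UK primary-care research.

## Windows (stage 1)

For each practice: `practice_start = max(key_date + offset, study_start)`
and `practice_end = min(study_end, collection_date)`, where `key_date` is
the latest of the practice's computerisation / acceptable-mortality-rate /
healthcare-system dates (they act as a unit, so they are combined at load)
and the offset is a data-quality lead-in in days. For each patient:

```
patient_start = max(registration + lead-in, practice_start, attains(entry_age_min))
patient_end   = min(practice_end, deregistration, death, last day at age <= exit_age_max)
```

Rejections are recorded against the *first* failing check, in the fixed
order: entry age exceeded, sex filter, window overlap, empty window. A fixed
order makes attrition tables reproducible across runs and versions.

## Code entities and exposure logic (stage 2)

A **code entity** is a named set of clinical codes plus a qualification
rule. Inclusion rules:

* `incident_only` — the earliest record on or before `patient_end`
  qualifies; if it falls *before* `patient_start` the patient is rejected
  as prevalent-at-entry (their onset is unobserved, so they can be neither
  a clean incident case nor an unexposed control).
* `incident_or_prevalent` — the earliest record on or before `patient_end`
  qualifies even when it precedes entry; a pre-entry record contributes the
  **patient start date** as its date, because a prevalent exposure puts the
  patient at risk from the moment they are observed. This also keeps every
  index date inside the observation window.
* `first_after_entry` — the earliest record inside the window qualifies.

Exclusion rules: `exclude_ever` (any record at any time, including after
the window — "ever" means ever) and `exclude_before_index` (a record on or
before the index date). Pre-index checks are inclusive of the index day:
a same-day prior event is treated as prevalent, which is the conservative
reading and prevents an outcome recorded on the index date from being
counted as incident follow-up.

Entities combine through a boolean grammar:

```
expr   := term ("or" term)*
term   := factor ("and" factor)*
factor := NAME | "(" expr ")"
```

`and` binds tighter than `or`; keywords are case-insensitive; there is no
`not` — negative criteria are exclusion entities, which keeps every
expression monotone and every index date well defined.

**Loose evaluation** ignores order. A conjunction is satisfied when both
operands are and contributes the later date (the criterion is only complete
when its last component occurs); a disjunction contributes the earliest
date at which the whole expression became true. Equivalently: over all
subsets of the patient's present entities that satisfy the expression, the
index is the minimum of the subsets' latest dates. The test suite checks
this equivalence exhaustively over small expressions.

**Strict evaluation** additionally requires the entities to have occurred
in the order written: within every conjunction chain, dates must be
non-decreasing left to right. Equal dates count as in-order — a same-day
diagnosis and prescription is a valid sequence. Disjunction branches are
*alternatives*: the order constraint never crosses an `or`, because order
is a property of a sequence and a disjunction is a choice between
sequences. A patient who satisfies the expression in some order-respecting
way receives the earliest achievable qualifying date; one who satisfies it
only out of order is discarded with reason "exposure order violated"
(distinct from simply not qualifying); one missing a needed entity is
unsatisfied and becomes a potential control when the design requires
controls.

Patients failing the logic in a cross-sectional design are retained as
unexposed rows rather than discarded: a prevalence estimate needs its
denominator.

## Control pool (stage 3)

When control logic is declared, the same locate/evaluate machinery runs
over the pool; failures are documented rejections. Only `exclude_ever`
exclusions apply here — controls have no index date yet, so index-relative
exclusions belong to matching. The logic's entity date is kept as a
provisional column only; a matched control's real index date comes from its
exposed partner, which is the standard device against immortal time bias
(a control's follow-up must not begin at a time chosen with knowledge of
their survival).

## Matching (stage 4)

Both the exposed list and the pool are shuffled with the seeded generator;
for each exposed in shuffled order the pool is filtered through the
criteria and `min(n_required, eligible)` controls are drawn uniformly
without replacement. Selected controls leave the pool; group ids are
assigned consecutively in processing order. This greedy sequential design
is deliberately simple: it is reproducible under a single seed and
its behaviour is easy to verify (an independent re-check of every emitted
pair is part of the test suite). No global optimisation is attempted.

Criterion semantics, in the order applied:

* sex: same / any / opposite;
* the control's window must cover the index date;
* age at index within ± the tolerance (completed years);
* Townsend quintile and ethnicity: concordance when requested (two missing
  values are treated as concordant);
* registration date: absolute difference in days within the tolerance —
  the alternative reading (registered duration at index) differs only by
  which difference is taken and is noted in the source;
* exposure duration: |first record(control) − first record(exposed)| within
  the tolerance, both relative to the same shared index; a control without
  the record is ineligible; the criterion is vacuous when the exposed has
  no record;
* baseline treatments and conditions: presence-concordance — the control
  has a pre-index record of the entity exactly when the exposed does
  (matching means *same status*, not *has the condition*);
* measurements: the control's latest value within the lookback window
  before index must lie within ± the tolerance of the exposed's
  corresponding value; when the exposed has no value in the window the
  criterion filters nothing (a missing exposed value cannot define a band);
* listed outcomes/events on or before the index date disqualify.

Exposed members with no eligible control are kept by default, flagged
unmatched, and reported in the extraction result; a matched-analysis user
can set the policy to `drop`, in which case they are logged as rejections.
The distinction matters for the audit arithmetic: the rejection log counts
*removals* only, so that at every stage `in = out + rejections` holds
exactly — a kept-unmatched exposed is not a removal. Pool members never
selected are logged as "potential control not selected".

## Outcomes and exit (stage 5)

For each member and outcome entity the earliest event **strictly after**
the index date and on or before the patient end date is recorded. Searching
strictly after index complements the inclusive pre-index convention: no
event can be both an exclusion trigger and an incident outcome, and a
same-day outcome cannot create zero-length immortal follow-up. The exit
date is `min(patient_end, first outcome of any kind)`; per-outcome dates
and days-to-event are also emitted so analysts can apply cause-specific
censoring. Exits are per-patient: whether a matched control should be
additionally censored at its partner's exit is an analysis choice, not an
extraction rule, so it is left to the analyst.

## Assembly, summaries and encryption (stage 6)

Baseline rules are `latest_before_index` (optionally restricted to a
lookback window), `earliest_ever` and `first_after_index`; measurement
entities yield values, diagnosis/treatment entities presence flags, absence
a missing marker (empty field in CSV, consistent with the input
convention). Column order is deterministic and two runs with the same seed
and inputs produce byte-identical files.

Incidence uses person-years = follow-up days / 365.25 (fixed documented
constant) and reports events per 100,000 person-years with the exact
Poisson interval (chi-square form: lower = qchisq(α/2, 2E)/2,
upper = qchisq(1−α/2, 2E+2)/2, scaled); prevalence on a reference date uses
members whose window covers the date, with the exact Clopper–Pearson
interval. Both are cross-checked in the tests against `poisson.test()` and
`binom.test()`.

Encrypted output uses encrypt-then-MAC: AES-256-CBC for confidentiality and
HMAC-SHA-256 over header and ciphertext for authenticity, both keys derived
from the password by the salted, iterated bcrypt KDF. The container stores
a one-byte format version with the KDF parameters, salt and IV, so the
layout can migrate. A wrong password or a flipped bit fails the MAC check
loudly — decryption never returns silent garbage.

## Audit and checkpoints

Every rejection increments a (stage, reason) counter — a new reason enters
the map with count 1 — and the attrition table derived from the log is
checked against the per-stage in/out counts; an imbalance is a hard error,
because verifiability is the point of the exercise. An extraction log
(timestamp, SHA-256 digests of the design and database, seed, version,
per-stage counts, status) is written for every attempt, including failures.

After each stage the member table and logs are checkpointed as CSV/JSON
under the output directory; a resumed run validates the digests and seed
before reusing a checkpoint and reproduces the uninterrupted run
byte-for-byte. Only stage 4 consumes randomness, and it seeds its own
generator from the design seed (saving and restoring the caller's RNG
state), so resume-equivalence is structural rather than accidental.

## The synthetic population

`simulate_ehr()` draws a THIN-like database: practices with key/collection
dates; patients with sex, birth year (a configurable fraction
year-precision), registration, and competing exponential deregistration and
death clocks; Townsend quintiles and ethnicity; BMI and HbA1c measurements
at a per-person-year rate with a missingness fraction. The planted
epidemiological structure is:

* **exposure** — first occurrence from a per-year Bernoulli incidence while
  registered, optionally followed by a prescription record at a fixed lag
  (to exercise order-sensitive logic), plus an optional *prevalent
  fraction* carrying the exposure from registration day one (to plant a
  point prevalence for cross-sectional studies);
* **outcomes** — a piecewise-rate Poisson event stream: rate λ₀ before the
  patient's first exposure event and λ₀ × HR after it.

Outcome events *recur* rather than occurring at most once. This mirrors
coded outcomes in real records, and it matters for validation: a Poisson
stream has independent increments, so post-index event risk is unaffected
by any selection on pre-index history. With a single-event clock,
without-replacement matching that excludes controls on outcome history
couples the draw to the event time — controls whose only event falls just
after a candidate index are preferentially available for it — and at the
pool utilisations of a desk-scale study (here roughly half the pool is
consumed) this inflates the recovered control rate by on the order of 20%.
For the same reason the reference validation design
(`validation_cohort_design()`) matches *blind to outcome history* and
defines its estimand as the first post-index event: that makes the planted
rates exactly recoverable at any pool size. In real-database use, where the
pool dwarfs the case list, the history-excluding criteria behave as
intended and remain available.

Constant hazards are a deliberate simplification: the pipeline's
correctness claims concern extraction, not survival-model realism, and
closed-form expected rates make every tolerance computable. What the
generator does **not** emulate: age- or calendar-dependent hazards,
informative censoring, realistic code dictionaries and miscoding,
practice-level clustering of covariates, or measurement error structure.
Passing the recovery tests therefore demonstrates that the *extraction
machinery* is unbiased under known data-generating conditions — not that
any given real-world study design is.

Default generator conditions: 20 practices × 2,500 patients over
1998–2019, exposure incidence 1%/year, unexposed outcome rate 44 per
100,000 person-years with hazard ratio 3 — the magnitudes of a primary-care
epilepsy cohort — yielding a matched 1:4 cohort with roughly 220,000
person-years of follow-up and 60–80 unexposed events. The cross-sectional
validation plants a 3.3% point prevalence in a population of 12,000. These
sizes give each recovered quantity a Monte-Carlo coefficient of variation
near 10% while a full validation run completes in well under a minute.

## The worked example

`worked_toy()` is a fixed 40-patient, three-practice database in which
every patient is constructed to exercise one documented path: in-order and
out-of-order strict sequences, prevalent-at-entry records, a pre-index
outcome, an ever-recorded exclusion, a year-precision birth date, death and
deregistration censoring, an exposed teenager with no age-compatible
control, and a practice whose collection stopped before the study starts.
Its companion `toy_design()` is a strict "Diabetes and Metformin" matched
cohort with a stroke outcome. The stage-by-stage fate of every patient was
derived by hand from the rules above, is asserted patient-by-patient in the
test suite, and the resulting dataset and attrition table are frozen as
golden files that the full pipeline must reproduce exactly.

```{r toy, eval = FALSE}
res <- run_extraction(worked_toy(), toy_design(), out_dir = tempdir())
glance(res)   # 18 rows: 7 exposed, 11 matched controls, books balanced
tidy(res)     # the attrition table
autoplot(res) # rejection counts by stage and reason
```

## Known limitations

* Index-relative control exclusions are evaluated at matching time only;
  a control acquiring an exclusion *after* its index date is retained, as
  the procedure specifies.
* The grammar has no `not` and no temporal-gap constraints ("A then B
  within 90 days"); new-user and prevalent-new-user designs are out of
  scope.
* Matching is greedy per shuffled exposed, not globally optimal: an
  unlucky order can leave an exposed unmatched even when a feasible global
  assignment exists. This is the documented, reproducible behaviour of the
  procedure rather than a defect, but users with scarce pools should
  prefer larger tolerances or fewer controls per exposed.
* Expressions that reference the same entity more than once are evaluated
  correctly but the equivalence tests cover distinct-leaf expressions, the
  only forms that arise naturally.
* A single source database per run: multi-source merging and common-data-
  model conversion are not attempted.
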
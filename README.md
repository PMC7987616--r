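# ehretl

Automated, verifiable extraction of analysable study datasets from
longitudinal primary-care records.

Epidemiologists working with THIN/CPRD-style databases (practices →
registered patients → coded clinical, therapy and measurement events) spend
most of a study's effort turning raw tables into one clean row per subject:
eligibility windows, exposure definitions, matched controls, outcomes,
baseline covariates. `ehretl` implements that process as a six-stage
extract–transform–load pipeline in which the study design is data, every
discarded patient is counted against a documented reason, and a whole run
is reproducible from a single seed. It supports cohort, case–control and
cross-sectional designs, and ships a seeded synthetic-records generator
with planted epidemiological structure so the entire pipeline can be
validated end-to-end without access to any licensed database.

## The pipeline

| Stage | What it does |
|---|---|
| 1 Eligibility | practice window `[max(key date + offset, study start), min(study end, collection)]`; patient window from registration, death/deregistration and age limits |
| 2 Exposure/cases | locate code entities (`incident_only`, `incident_or_prevalent`, `first_after_entry`), evaluate boolean exposure logic (strict = order-sensitive, loose), assign index dates |
| 3 Control pool | non-qualifying patients optionally refined by control logic |
| 4 Matching | seeded, without-replacement selection of *n* controls per exposed on sex, age, Townsend, ethnicity, registration, exposure duration, baseline status, measurement values; controls inherit the exposed's index date (immortal-time protection) |
| 5 Outcomes | first event strictly after index per outcome; exit = min(window end, first outcome) |
| 6 Assembly | baseline extraction, wide dataset, attrition table, audit log, optional AES-256 output encryption |

Exposure logic is a small grammar over declared entities —
`"Type2Diabetes and Metformin"`, `and` binding tighter than `or` — with two
evaluation modes: *loose* (index = latest date needed to satisfy the
expression) and *strict* (conjunction operands must also occur in
left-to-right date order; out-of-order patients are discarded with a
documented reason).

The audit invariant, enforced at run time, is per-stage conservation:

    patients in = patients out + Σ logged rejections

Incidence summaries report events per 100,000 person-years
(person-years = days / 365.25) with exact Poisson 95% intervals; prevalence
on a reference date uses exact Clopper–Pearson intervals.

## A worked example

The package includes a fixed 40-patient toy database in which every
patient exercises one documented pipeline path, plus its companion matched
cohort design (strict "Diabetes and Metformin", 2 controls per exposed,
stroke outcome):

```r
library(ehretl)
res <- run_extraction(worked_toy(), toy_design(), out_dir = tempdir())
res
#> <ehr_extraction> cohort design: 18 rows (7 exposed/case)
#> stage flow:
#>   stage1: 40 -> 35
#>   stage2: 35 -> 29
#>   stage3: 29 -> 29
#>   stage4: 29 -> 18
#>   stage5: 18 -> 18
#>   stage6: 18 -> 18

tidy(res)   # attrition: stage, documented reason, count
#>   stage  reason                                        count
#> 1 stage1 older than maximum entry age at patient start     1
#> 2 stage1 patient window outside practice window            2
#> 3 stage1 practice window empty                             2
#> 4 stage2 exclusion (ever recorded): Palliative             1
#> 5 stage2 exposure order violated                           2
#> 6 stage2 outcome before index: Stroke                      1
#> 7 stage2 prevalent at entry: Diabetes                      2
#> 8 stage4 potential control not selected                   11
```

Forty patients in; 5 rejected at eligibility, 6 at exposure definition
(two had metformin *before* diabetes — the strict order rule — two were
prevalent at entry, one had a pre-index stroke, one a palliative-care
exclusion code); 7 exposed matched to 11 controls; the 11 never-selected
pool members are accounted for. 18 rows + 22 rejections = 40.

`summarise_incidence(res$dataset, "Stroke")` then gives per-group events,
person-years and rates; `autoplot(res)` draws the attrition profile.

Designs round-trip through plain config files
(`write_study_design()` / `read_study_design()`), databases through CSV
(`write_ehr_db()` / `read_ehr_db()`), and a thin command-line front end is
installed at `system.file("cli", "ehretl.R", package = "ehretl")` with
`extract`, `simulate` and `summarise` subcommands.

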
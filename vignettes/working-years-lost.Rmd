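---
title: "Accounting for working life years lost: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for working life years lost: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(wyloss)
```

## The metric

`wyloss` measures workplace disease burden as the number of working life
years a workforce loses to ill health, per 10,000 person-years of working
time supplied ("per myriad"). Three consequences are accounted jointly:

* **sickness absence (SA)** — medically certified long-term spells
  (≥ 30 consecutive days) from which the employee eventually returns;
* **mortality** — once an employee dies, every remaining working day up to
  the end of their personal window is lost;
* **ill-health retirement** — likewise from the retirement date onward,
  attributed to the illness that caused the terminating spell.

The joint treatment is the point: a burden measure restricted to mortality
misses chronic illness that keeps people off work for months, while a
morbidity-only measure misses fatal disease with little preceding absence.
Counting calendar time lost puts both on the same scale.

## The clipping calculus

Every event span is intersected with the employee's *personal window*,
`[max(window start, 20th birthday), min(window end, 60th birthday))` —
time outside the study frame or outside working age cannot be lost. All
intervals are half-open (`[start, end)`). This single convention settles
several otherwise fiddly cases:

* abutting spells share no day, so merging and summing are consistent;
* an employee dying *on* their 60th birthday contributes zero mortality
  burden (the window is already closed);
* a spell ending on the window start date contributes nothing.

When a spell terminates in death or retirement, the SA contribution stops
on the event date and the terminal contribution starts that same date — a
zero-gap handoff with no shared day. The per-employee engine
(`compute_burden()`) is pure interval arithmetic; the test suite pins it,
case by case, to a brute-force oracle that walks every calendar day of
1,000 randomized employees and labels each day independently.

### Assumptions

* At most one terminal event per employee; conflicting records (two
  terminal spells, a retirement spell plus a death certificate) are data
  errors, not modelling choices.
* A death can truncate a recorded spell, but a recorded death predating a
  spell's start is rejected.
* Leaving employment for non-health reasons is not modelled, so the
  retirement component is, if anything, an overestimate: some ill-health
  retirees may work elsewhere later. This is a known limitation of the
  records this package is built for.
* The survival effect (less-healthy workers leaving the workforce early)
  is inherent in the data-generating reality; burden in older strata is
  biased downward by it and the package does not attempt to correct that.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| observation window | 2012-04-01 to 2018-03-31 | dates | six fiscal years; any half-open range works |
| working age | 20–59 | years | 60 is the statutory retirement age assumed |
| LTSA threshold | 30 | days | the boundary between short spells (absorbed by paid leave) and long-term illness |
| day→year divisor | 365.25 | days/year | calendar-stable across leap years |
| CI level | 0.95 | — | convention |

Two decisions deserve explanation:

* **The 30-day filter applies to the raw spell, before clipping.** A
  9-month spell of which ten days fall inside the window is still
  long-term illness; it passes the filter and then contributes its ten
  in-window days. Filtering after clipping would make a spell's
  classification depend on the study frame, which is epidemiologically
  wrong.
* **Overlapping spells with different diagnoses are errors.** Overlaps
  within one disease group are merged (they are one illness episode seen
  through several certificates); overlaps across groups cannot be resolved
  without inventing an attribution rule, and silently guessing would
  corrupt the group decomposition. Surfacing dirty HR data beats guessing.
  A merged spell takes its diagnosis from its earliest constituent and its
  outcome from its latest-ending one; a terminal outcome anywhere else in
  a merged cluster is rejected (nothing can follow a death).

## Diagnosis grouping

Grouping uses only the three-character ICD-10 base code (certificate
sub-codes never change a chapter). The 20 categories are the standard
chapter blocks with one rearrangement: injury/poisoning (S00–T98) and
external causes of morbidity and mortality (V01–Y98) are pooled, and
intentional self-harm (X60–X84) is carved out as its own category, so that
suicide — a major contributor to workplace mortality burden — is visible
rather than buried among accidents. The endocrine block is accepted as
E00–E99 (E91–E99 are unused in ICD-10, so the wider bound is harmless).
Codes outside every block — the perinatal chapter (P), U-codes, and gap
codes such as D49, T99, V00 or Y99 — error by default; an `"unclassified"`
bucket is available for exploratory runs. An exhaustive scan of all 2,600
three-character codes against an independently stated range table is part
of the test suite.

## Denominator and inference

Headcounts arrive as annual counts by sex and 5-year age band; each
counted head contributes exactly one person-year, because annual counts
are the finest information such records carry. Any finer convention
(fractional person-years for mid-year hires) would be an invention the
input data cannot support; the choice is documented rather than asserted
as universal.

The 95% interval treats the person-years lost `L` in a cell as a Poisson
count: `(L ± z√L) / D × 10,000`. No distributional claim fits perfectly —
`L` is a compound sum of spell durations, not a count — but for losses
dominated by spells much shorter than a year the compound variance
`λ·E[duration²]` is *below* the Poisson-assumed `λ·E[duration]`, so the
interval errs conservative. The test suite verifies ≥ 93% empirical
coverage of a known rate over 500 simulated cohorts, and interval width
shrinking as `1/√D`. The stratum comparison is a 1-df chi-squared test on
the 2×2 table of person-years lost vs not lost, rounded to whole
person-years because the test assumes counts; `stats::chisq.test()`
(uncorrected) provides the computation and a direct `Σ(O−E)²/E` evaluation
cross-checks it in the tests.

Age-stratified tables assign each *burden day* to the age group the
employee occupies that day, splitting contributions at the 40th-birthday
boundary. This keeps the stratum decomposition exact: the four sex × age
cells sum to the overall row to machine precision, which the tests assert
without rounding slack. Internal arithmetic is never rounded; one-decimal
rounding exists only in the report renderer.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` reproduces the *record structure* of a multi-company
occupational cohort: a roster with sex and birth dates, spell tables whose
durations can straddle the window edges and the 20th/60th birthdays,
terminal outcomes, death certificates without preceding absence, and
April-1 headcounts by sex and 5-year band. Defaults were fixed once, as a
plausible large-workforce scenario, and are not tuned per test:

* male share 0.81 — matching the person-year sex split typical of large
  Japanese industrial cohorts;
* ages uniform over 18–59 at the window start, so both age-boundary
  clipping paths occur;
* spell onsets: homogeneous Poisson per employee and diagnosis code
  (default total 0.014/person-year across six representative codes, F32
  dominant);
* durations log-normal, meanlog `log(60)`, sdlog 1 (median 60 days, heavy
  right tail; many draws fall under the 30-day threshold on purpose, so
  the filter has work to do);
* outcomes return/retirement/death = 0.86/0.10/0.04 per spell; direct
  deaths at 4 × 10⁻⁴/person-year across three causes.

Resolution rules keep the generated tables consistent with the accounting
preconditions: overlapping draws for one employee are resolved by keeping
the earliest spell, and the first terminal outcome censors everything
later. The generator makes no attempt at disease-specific epidemiology
(age- or sex-specific incidence, seasonality, duration-by-diagnosis), so
passing tests demonstrate that the *accounting* is correct under a
realistic record structure — not that any particular workforce's burden
profile is reproduced.

`expected_burden()` is the reference for recovery tests: the average of
the full pipeline over independent replicates (seed schedule
`seed + 1 … seed + n_reps`). Because the reference is itself Monte Carlo,
recovery tests compare an estimate to it using the standard error of the
*difference*, `sd·√(1 + 1/n_reps)`, at three SEs.

## Numerical choices and degenerate inputs

* Dates are handled as R `Date` objects throughout; birthday arithmetic
  rolls Feb-29 back to Feb-28 in non-leap years.
* Disjoint interval intersections return an *empty* interval, never an
  error; empty contributions are dropped, so an employee with no in-window
  loss simply has no rows.
* An empty episode table yields a complete all-zero burden table.
* A stratum with no headcount rows is dropped if it also has no burden,
  and is an error if burden exists — burden without a denominator means
  the inputs are inconsistent.
* Zero years lost gives the degenerate interval (0, 0).
* All randomized tests take explicit seeds; the simulator restores the
  caller's RNG state.

## Problem sizes used by the test suite

Chosen as the package's own verification budget: oracle agreement on
1,000 randomized employees; marginal-identity checks on a matrix of three
2,000-employee cohorts; single-group parameter recovery at 50,000
employees against a 20-replicate reference; coverage on 500 cohorts of
1,500 employees against a 100-replicate reference. The whole suite runs in
a few minutes on one CPU.

## Known limitations

* Retirement burden is an upper bound (no re-employment model).
* Short-term (< 30-day) and self-reported absence, and presenteeism, are
  out of scope; burden from diseases that mostly cause short spells
  (e.g. musculoskeletal complaints) is correspondingly understated.
* No age-standardisation and no multiple-testing correction are provided;
  stratum chi-squared p-values are raw.
* The Poisson interval is approximate; for cells dominated by a handful of
  multi-year terminal losses it can be anti-conservative, which is why
  coverage is verified by simulation for the spell-dominated regime the
  metric targets.
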
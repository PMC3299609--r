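---
title: "Methods: cost-of-illness modelling for shoulder pain in primary care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-of-illness modelling for shoulder pain in primary care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shouldercoi)
```

## The problem and the modelling approach

Shoulder pain is mostly managed in primary care, and its societal cost is
dominated not by consultations or imaging but by sick leave concentrated
in a small minority of patients. This package implements a prospective,
bottom-up cost-of-illness model over a six-month measurement window:
every individually recorded resource-use event (GP visit, physiotherapy
treatment, x-ray, ultrasound, filled prescription) is valued with a unit
cost, sick leave is valued as lost production, and costs are aggregated
per patient and per cohort.

The model is deliberately linear: per-patient cost is a dot product of
unit counts and unit prices. Everything downstream exploits that
linearity — component shares, the deterministic sensitivity engine, and
the exact closed-form oracle the tests compare it against.

## Cohort definition

Patients qualify when aged 20–64 (inclusive), resident in a study
municipality, and at least one visit in the window carries a qualifying
ICD-10 code. Twenty-nine codes in four clinical categories qualify:
subacromial/nonspecific pain, stiffness, fractures, dislocations.
Matching is exact on the normalised code (dots and whitespace stripped,
upper-cased); range tokens such as `M751-9` expand over the last digit.
A patient whose visits span several categories is assigned the category
of the first qualifying visit — no clinical precedence is defensible
from coded data alone, and first presentation is the natural
tie-break in a prospective design.

### Treatment episodes

The treatment episode runs from the first to the last qualifying visit
with no disallowed gap. "At least one visit per month" is
operationalised as a maximum inter-visit gap of 31 days — the longest
calendar month — doubled to 62 days when the gap interval overlaps the
holiday window (default July 1–August 15, the Swedish primary-care
holiday season). Doubling, rather than ignoring the rule entirely across
the holiday, keeps the episode definition bounded; it is a design choice
where the prose admits several readings.

Durations fall into four reporting bands using half-open day intervals:
`[0, 42]`, `(42, 84]`, `(84, 182]`, `(182, ∞)` days. The 7–12-week and
12–26-week labels overlap at week 12; we assign days 78–84 to the
7–12-week band so every duration lands in exactly one category.

## Costing

Default unit costs (euros, 2009 Swedish price level):

| item | default | unit |
|---|---|---|
| GP visit (25 min) | 107 | per visit |
| Physiotherapy (60 min) | 50 | per treatment |
| X-ray, shoulder | 65 | per examination |
| Ultrasound, shoulder | 124 | per examination |
| Medicine | 12.4 | per filled prescription |
| Orthopaedic specialist | 335 | per outpatient visit |
| MRI | 308 | per investigation |
| Ambulatory shoulder surgery | 2420 | per operation |
| Sick leave | 205 | per full day |

The per-prescription medicine price is not part of the published price
schedule (drugs were priced individually); 12.4 is the cohort's
medication total divided by its prescription count and can be replaced
by users with drug-level prices. The €205/day sick-leave price embeds
the human-capital formula `income × (1 + 0.40 + 0.28)` — wage plus
social fees plus indirect taxes; `daily_productivity_cost()` is exposed
for users with their own regional income data (205/1.68 ≈ €122/day
implied mean income).

### Sick-leave day equivalents

Prescriptions carry a grade (25/50/75/100% of full working time).
Overlapping prescriptions are merged day by day at the maximum grade;
days are clipped to the measurement window. The default
`graded_weighting` policy counts each day as grade/100 of a full day.
This is a substantive choice: the published per-patient sick-leave cost
(€1743 ≈ 1735 day-equivalents × €205 over the cohort) is consistent
only with graded weighting, not with the listed 1844 calendar days at
full value (which would give €378k, not €356k). A `full_day` switch
retains the alternative reading.

### Friction-cost valuation

The friction-cost method replaces the human-capital assumption (all
absence is lost production) with a friction period until a replacement
worker is productive, operationalised as a fixed factor 0.387 applied to
the human-capital value. Friction-valued totals are therefore bounded
above by human-capital totals patient by patient — a package invariant
under test.

### Secondary care and annualization

Referrals, MRIs and ambulatory surgeries are costed as counts × prices
(`estimate_secondary_costs()`); with the study's 29 referrals, 10
estimated MRIs and 4 surgeries this prices out at €22,475. Six-month
costs are doubled for an annual estimate, which assumes stationary
patient through-flow across the year.

## Cohort statistics

Means, SDs, medians and quartiles are computed per component; the 95%
interval for a mean is the normal approximation `mean ± 1.96·sd/√n`.
The z-based interval (not t, not bootstrap) is chosen because it exactly
reproduces the published intervals (2069 ± 786 → 1283–2856 from
sd 5730, n 204), identifying it as the construction used upstream; at
n ≥ 200 the z/t difference is under 1%. Medians use the inclusive
quartile convention. No multiple-testing adjustment is applied anywhere.

When the input is a printed-margins table rather than patient-level
data, means are `total/n`, SDs are as printed, and medians/quartiles are
reported `NA`: they are not recoverable from margins.

The log-cost regression (`fit_log_cost_regression()`) is OLS of
log(cost) on place of treatment, gender and age. Zero-cost patients are
excluded (log undefined) and the exclusion count reported; constant or
collinear covariates raise an error naming the term rather than fitting
a deficient design.

## The sensitivity engine

A scenario is a set of relative price changes plus an optional
friction-method switch. Because frequencies are held fixed and the model
is linear, the engine's percent change for a one-way scenario must equal
`δ × component share × 100` exactly; the test suite enforces agreement
with this closed form at 10⁻¹² relative tolerance, and multi-way
scenarios must superpose. Perturbed confidence intervals are recomputed
from the perturbed patient-level distribution when patient-level data is
available; from margins alone they are reported as unavailable (the
component covariances needed to propagate a price change into a total
SD are not printed) except for aggregates the scenario does not touch.

One default-scenario choice deserves a note. The published four-way
scenario is labelled "PT, GP, x-ray, ultrasound per consultation", but
its printed means (total 2186, healthcare 443) are reproduced only when
the medicine price also moves ±30% (exact values 2186.3 and 443.1,
versus 2185.3/442.1 without medicine). The default scenario set follows
the numbers rather than the label and perturbs all five healthcare
prices in that scenario.

Rendered reports round euros half-up to whole euros and percentages
half-up to one decimal, matching the precision conventions of published
cost tables; all internal arithmetic is full double precision.

## The synthetic-EPR generator

The generator emulates the statistical structure the analysis assumes:
a 204-patient cohort over a 181-day window, 103/204 women, truncated-
normal ages (mean 48, SD 11, range 20–64), diagnosis categories in
proportions 181/10/7/6, GP visits with mean 0.89/SD 0.97, physiotherapy
visits with mean 3.91/SD 7.40 and a third of patients with none,
per-patient imaging probabilities 57/204 and 23/204, prescription
probability 58/204, 20% of patients with any sick leave, overall
sick-leave days mean 9.04/SD 29.17, and 11% of sick-leave days at
partial grades drawn uniformly from {25, 50, 75}% (the source states the
grade range but not its distribution).

**Why a hurdle model, not a zero-inflated negative binomial.** The
physiotherapy targets are jointly infeasible for a ZINB: a negative
binomial matched to mean 3.91 and SD 7.40 already has P(0) ≈ 0.45, and
zero-inflation can only increase the zero share — the minimum over the
ZINB family is ≈ 0.40, above the observed 1/3. The data are
zero-*deflated* relative to NB. Visit counts therefore use a hurdle:
P(0) = zero share, positive counts 1 + NB(μ, k), which moment-matches
the three targets in closed form.

**GP counts guarantee a consulter.** An EPR extract only contains
people who consulted, so every synthetic patient needs ≥ 1 visit. GP
counts are drawn conditionally: patients with no physiotherapy draw
1 + NB(μ, k), the rest NB(μ, k), with μ and k solved so the marginal
mean and variance equal the configured targets exactly in expectation.

**Sick-leave durations** are log-normal with the log-scale variance set
from the conditional coefficient of variation and the location solved
numerically so the *window-capped* conditional mean equals
mean/any-probability (45.2 days); without the cap adjustment, clipping
at the 181-day window would bias the overall mean ≈ 5% low. Incidence
is tilted towards heavy physiotherapy users (a rank-based weight with a
configurable dependence strength, default 1) while preserving the
marginal 20% — this co-locates long absences with high utilization and
produces the heavy tail in which the top fifth of patients carry the
large majority of cohort cost. Each spell splits its final 11% of days
into a partial-grade prescription, so the partial share of days is
matched by construction.

**Visit dates** start uniformly in the window with inter-visit gaps
uniform on 3–28 days (within the 31-day episode rule, so each synthetic
patient forms one episode); gap sequences that would overrun the window
are compressed proportionally. Consequently synthetic episodes are never
censored at the window boundary and episode-duration margins are
emergent rather than calibrated — two known departures from real
extracts, where treatment spells straddle the window. The generator also
does not model comorbidity, employment status, co-payments or real
personal-identity-number formats.

What passing calibration tests show, therefore, is that the pipeline
recovers the configured utilization and cost structure from EPR-shaped
tables — not that the generator reproduces every printed margin. Indeed
no synthetic cohort can: the printed unit counts × unit prices disagree
with the printed component totals at the €10–60 level (e.g. 181 GP
visits × €107 = €19,367 vs the printed €19,429), so the packaged
margins fixture, which carries the printed totals verbatim, is the
canonical input for reproducing published aggregates, and the generator
targets per-patient means instead.

## Problem sizes and tolerances in the test suite

Monte-Carlo calibration uses 200 replicate cohorts of 204 patients
(means within ±0.05 for GP and ±0.3 for physiotherapy visits, about
ten standard errors of headroom); cost-concentration checks use 60
replicates against a conservative 60% bound for the top-quintile share;
regression parameter recovery injects a gender effect of 0.5 on the log
scale at n = 2000 and requires recovery within ±0.15 (≈ 3 standard
errors); null-effect coverage uses 100 replicates at n = 204. The
linearity oracle is enforced at 10⁻¹² relative tolerance; printed-table
reproductions are asserted at the precision the tables print (±0.1
percentage point, whole euros half-up).

## Known limitations

- Costs are attributed to the primary shoulder diagnosis only;
  comorbidity-driven cost is out of scope, as are patient co-payments,
  cost ceilings and over-the-counter medication.
- Sick leave shorter than the prescription threshold (about a week) and
  surgeon-prescribed postoperative sick leave are invisible to a
  GP-record extract, so indirect costs are a lower bound.
- The secondary-care figure is an estimate from referral counts and
  list prices, not observed hospital billing.
- The regression procedure is implemented and tested on synthetic data;
  published coefficient values are not reproducible without the
  original patient-level records.
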
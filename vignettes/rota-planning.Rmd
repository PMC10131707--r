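---
title: "Rota planning for hub-and-spoke telehealth services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rota planning for hub-and-spoke telehealth services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telerota)
```

## The planning problem

A hub-and-spoke telehealth service — the motivating case is a child and
adolescent mental health (CAMHS) liaison team — assesses patients either
on site at hospital "spokes" or remotely by video from a central hub.
Each day, each practitioner is either off or works exactly one place:
one of the hospitals, or the hub. On-site days cost round-trip miles;
hub days cost none. The planning question is which practitioner works
where on each day of a horizon, such that the expected patient demand at
every location is covered.

The model is a binary integer program. With staff $i \in I$, locations
$l \in L$, days $t \in T$, per-day treatment capacity $w_i$, expected
demand $d_{l,t}$ and round-trip miles $m_{i,l}$, the decision variables
are $x_{i,l,t} \in \{0,1\}$ ($1$ iff $i$ works at $l$ on $t$) and the
two objectives are

$$\min z_1 = \sum_i \sum_l \sum_t x_{i,l,t}
\qquad\text{(fewest staff-day assignments)}$$

$$\min z_2 = \sum_i \sum_l \sum_t m_{i,l}\, x_{i,l,t}
\qquad\text{(fewest miles travelled)}$$

subject to demand coverage and the one-place-per-day rule:

$$\sum_i w_i\, x_{i,l,t} \ge d_{l,t} \quad \forall l, t,
\qquad
\sum_l x_{i,l,t} \le 1 \quad \forall i, t.$$

Coverage is an inequality, not an equality: over-coverage is never
selected anyway because both objectives penalize every extra
assignment, and an inequality keeps instances feasible when capacities
exceed demands. Staff-day availability is preprocessing, not a
constraint — an unavailable staff-day simply contributes no variables —
which keeps the program small and keeps calendar logic out of the
solver.

In `lexicographic` mode (the default of the `run`/`schedule` pipeline)
$z_1$ is minimized first and then $z_2$ is minimized subject to
$z_1$ staying at its optimum. This is the recommended reading of "the
mile-minimal plan that still uses the fewest staff": under unit
capacities a pure $z_2$ solve already covers each demand unit with
exactly one assignment, but with heterogeneous capacities the pure
modes can genuinely differ, so all three are exposed.

## Exact solution by daily decomposition

No constraint couples two days: coverage is per location-day and the
assignment rule is per staff-day. The program therefore decomposes into
one independent subproblem per day, and the lexicographic compound
objective decomposes too (the horizon's stage-1 optimum is the sum of
the per-day minima, and any schedule attaining it attains each day's
minimum, so stage 2 may be run day by day with the day's stage-1 value
imposed as an equality).

Each daily subproblem — a few dozen binary variables at desk scale — is
solved exactly by a depth-first branch-and-bound implemented in C++
(`src/day_solver.cpp`). Branching is restricted to locations with
positive residual demand; this loses no optimum of a minimization
objective, because an assignment to an already-covered location could be
deleted from any solution claiming minimality. Pruning uses pooled
remaining capacity (feasibility), a largest-capacity-first bound on the
number of further assignments (staffing objective), and a
cheapest-remaining-fare-per-uncovered-location bound (miles objective).
First-found tie-breaking over a fixed staff order makes the search
deterministic; the `tie_break_seed` argument permutes that order so
alternate optima can be explored reproducibly without ever changing the
objective value.

The search is exact, so `solve_rota()` either returns the true integer
optimum or an infeasibility verdict. On infeasible days a max-coverage
relaxation (minimizing total unmet demand) produces a per-location
shortfall diagnostic; it is reported, never silently returned as a
schedule. The soft `time_limit` (default 60 s) is translated into a
search-node budget; the one-week case study solves in milliseconds, and
a 28-day, 8-staff horizon is a few hundred binaries split over 28
independent subproblems.

Because the specific optimal rota is generally not unique — the case
study's published rota is one of many 31-assignment solutions — the
package treats *objective values* as the reproducible surface and ships
an independent oracle, `brute_force_solve()`, which enumerates every
0/1 assignment on instances of at most 20 variables. The test suite
sweeps hundreds of seeded toy instances through both paths and requires
identical optima for all objective modes.

## The shipped case-study week

`cwtch_instance()` reconstructs the published one-week instance of the
CWTCH ("Connecting with Telehealth to Children in Hospital and
Healthcare") service: 8 practitioners, 3 hospital sites, the "AA"
(Attend Anywhere) telehealth hub, and the published distance matrix.
Two conventions come from the published tables: the hub costs zero
miles for everyone (remote work incurs no travel), and hub duty is a
demand-carrying assignment exactly like a hospital day, not a residual.

The case study never prints the demand matrix $d_{l,t}$ itself, so the
fixture derives it by counting, per location and day, the assignments
of the published minimum-staffing rota. Under unit capacities this is
the only faithful reconstruction available, and any demand with these
per-cell counts reproduces the published optimum of 31 assignments.
The published rota scores 416 miles against the distance table, the
published travel-minimal mileage grid re-totals to 47 miles, and the
difference — 369 miles a week — is the headline saving
(`headline_summary()`). The tests recompute all four numbers. Two
published figures are deliberately *not* chased: the "off duty 21
times" remark (8 staff × 7 days − 31 is 25, and a direct count of the
published OFF cells is also 25, so the package reports the recomputed
value), and the 47-mile plan as a *solver* output — the availability
and leave pattern behind the published week is unpublished, so with
full availability the true travel optimum of the fixture is 0 miles
(every hospital has a zero-mile practitioner), and 47 is reproduced
from the published grid instead.

## Demand forecasting

Daily referral counts are forecast per location by ordinary least
squares on calendar indicators: day of week (6), month (11) and a
bank-holiday flag, plus an intercept — 19 coefficients per location.
Reference levels are Sunday, January and non-holiday; the references
must be fixed somewhere for reproducibility, and Sunday/January make
the intercept the quietest baseline day. Separate per-location fits are
the default because site and weekday effects need not be proportional
across sites; `pooled = TRUE` fits one model with location dummies when
the per-site series are too short. The design matrix is built
explicitly with all indicator columns so short histories keep the fixed
coefficient layout; aliased columns (a month never observed, a holiday
flag that never fires) are dropped to zero with a warning rather than
silently renumbered.

Predictions clamp negative values to zero and round to integers —
`nearest` (half away from zero) by default, `ceiling` for a
conservative plan — because the coverage constraint consumes integer
demand and the rounding rule must be explicit. A floor of 20 records
per location (configurable) guards against unestimable designs.

Weekday summary statistics (`summarize_weekday_demand()`) report mean,
median, mode, minimum, maximum, range and total per weekday; the mode
takes the smallest most-frequent value on ties. The summary pools all
sites by default with an optional location filter, since service-level
tables of this shape are conventionally reported pooled.

## Availability from contract rules

Contracts are full-time (5 working days a week) or part-time (2-4
days). In each 4-week block every practitioner works 2 weekends — both
days, the default interpretation, because the published rota shows
staff working Saturday *and* Sunday of the same weekend; an
`either_day` mode is available — and takes leave within the block:
exactly 3 days full-time, 2 for 4-day part-timers, 1 otherwise. "About
three days" cannot be audited, so the package implements an exact,
configurable count. Leave lands on otherwise-available weekdays only,
so weekend rest is never double-counted as leave. Weekday availability
is drawn uniformly at random (seeded) to top each week up to the
contracted number of days; the seed moves *which* days are chosen,
never the per-week counts. Horizons that are not whole weeks are padded
to the next multiple of 7 and truncated after generation; blocks
shorter than 4 weeks scale the weekend and leave counts proportionally
(rounding half away from zero), both with warnings.

The arithmetic this fixes for a full-time practitioner over 28 days:
2 + 3 available days in each of the two worked-weekend weeks, 5 in each
of the others, minus 3 leave days — 17 available days, 4 of them
weekend days across exactly 2 weekends. `audit_availability()` checks
any calendar, generated or user-supplied, against these rules.

## The synthetic generator

`generate_instance()` emulates the structure of the case study rather
than any real series: distances uniform in a configurable range
(default 15-45 miles) with exactly one zero-mile home base per
practitioner; daily demand totals Poisson with the observed per-weekday
means of the service (Mon-Sun: 2.42, 2.65, 2.23, 2.16, 2.20, 1.29,
1.43), clipped to each weekday's observed range and split across
locations uniformly; a bank-holiday shift of −1 patient/day (holidays
behave like weekends, whose means sit about one patient below
weekdays); and a contract mix of 60% full-time, 20/10/10% part-time
4/3/2. Counts are small and weekday-dependent, which is what a Poisson
with weekday means captures; the case study does not state a
distribution. Demand is capped at the capacity available each day so
generated instances are feasible by construction (`allow_infeasible`
lifts the cap for stress tests).

`generate_demand_history()` produces regression fuel:
`round(max(0, lp + noise))` with caller-chosen weekday/month/holiday
coefficients and Gaussian noise. With zero noise and integer-valued
predictors the regression recovers the coefficients to numerical
precision, which the tests assert at 1e-8; with noise the rounding adds
a small oscillating bias (well under the 3-standard-error band the
recovery tests use). What the generator does *not* emulate: serial
correlation, seasonality beyond month effects, referral surges, or the
health board's true historical series — passing the recovery tests
shows the estimator is correct, not that real demand follows this
model.

## Problem sizes and numerical choices

The test suite runs at desk scale by choice: oracle sweeps use 200+
toy instances within the 20-variable enumeration bound, solver
properties use the 8-staff case-study shape over 1-4 weeks, forecasting
recovery uses two-year (n = 728) histories, and the availability sweep
uses 100 seeds — the whole suite completes in well under a minute.
All randomness flows through explicit integer seeds; generation,
solving and the CLI are bit-reproducible given the seed, and the
pipeline's JSON summary deliberately omits wall-clock timings so
identical runs produce byte-identical files. Degenerate inputs are
defined behavior: zero demand solves to an empty rota at objective 0,
missing demand cells are zero with a warning, and an all-constant
response fits to an intercept with zero residual SD.

## Limitations

Days are atomic (no morning/afternoon split), demand is deterministic
once forecast (no stochastic recourse or agency cover), and there is no
fairness or site-rotation constraint, skill mix, or staff preference
modeling. The solver is specialised to the daily decomposition; a
constraint coupling days (e.g. "at least one on-site day per
fortnight") would need the backend swapped for a general MILP solver
behind the same `build_model()` surface.
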
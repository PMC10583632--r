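---
title: "Modelling bed occupancy in municipal acute units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bed occupancy in municipal acute units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mausim)
```

Municipal acute units (MAUs) are small community inpatient units — in this
package's reference setting, four units of 6 to 72 beds — that admit
low-acuity acute patients who would otherwise go to hospital. Their key
performance indicator is the *absolute mean occupancy*: the average number
of beds occupied at the midnight census over a 365-day year. Because a full
unit turns referrals away (turned-away patients do not queue — a MAU is a
loss system), observed occupancy understates demand, and questions such as
"how much demand are we not seeing?" or "how many beds could a merged unit
save?" need a model. `mausim` implements that model end to end: a
discrete-time stochastic simulator, the regression sub-models that drive
it, the Erlang loss formula used to triangulate its estimates, scenario
experiments, and a synthetic-record generator that makes the whole pipeline
testable without patient data.

## The discrete-time engine

Time advances in fixed 24-hour steps; there are no intra-day event times
because admission data of this kind records only daily arrivals and
discharges. The engine maintains a list of inpatients, each tagged with the
unit its admission originated from, and updates it each day in five steps:

1. **Discharges.** Each inpatient is discharged during the coming day with
   probability given by the logistic discharge sub-model of its origin
   unit, by comparing a uniform(0,1) draw to that probability.
2. **Potential admissions.** Each unit draws a Poisson count of potential
   patients, with mean given by its linear admission sub-model for that
   date. Potential patients are pooled, tagged with their origin.
3. **Available beds.** Availability is the number of beds free at the
   start of the day plus a Binomial(D, 0.5) number of the D beds freed in
   step 1 — the *50–50 rule*: discharges and admissions actually happen at
   random times through the day, so a freed bed is usable for a same-day
   admission only about half the time. Each freed bed gets its own coin
   rather than one coin for the whole batch, matching the per-bed wording
   of the rule.
4. **Admission.** If potential patients exceed available beds, a uniformly
   random subset of the pooled list is admitted and the rest are turned
   away, so no origin unit is favoured; in unconstrained mode everyone is
   admitted.
5. **Update.** Admitted patients join the list with their origin tags.

The midnight census is recorded after the day's update — equivalently, it
is the occupancy entering the next day. Combined with the half-open
membership convention used for empirical records (a patient counts at the
midnights of `[admission, discharge)`), this makes the sum of the census
equal total patient-nights, and makes a census recomputed from emitted
records agree day-by-day with the engine's own trace. The instant of the
census relative to the day's updates is not observable in daily data; this
choice is the one that preserves those bookkeeping identities.

Each scenario is replicated (default `n_runs = 100`). A run simulates a
14-day warm-up from an empty unit (ample for stays averaging ~3 days), 365
core days that are scored, and a 7-day cool-down so stays begun near
year-end complete; warm-up and cool-down days are excluded from the score,
and turn-aways are counted over the core window only. The run value is the
mean census over the core days; the 95% confidence interval over runs uses
the normal approximation `mean ± 1.96 sd/√n_runs`. Every run draws from
its own substream, derived deterministically from the master seed, so
results are bit-reproducible and runs are order-independent.

## The two sub-models

**Admissions** are modelled in two steps: an ordinary least-squares
regression of the daily admission count on weekday and month as
categorical predictors (reference Monday and January), and a Poisson draw
whose mean is the regression prediction. Weekday and month are the
calendar factors consistently associated with admission volumes in this
setting; demographic variables and concurrent occupancy are deliberately
not predictors. A negative linear prediction — possible at sparse
parameter combinations — is clamped at zero before the Poisson draw, with
an optional warning, rather than treated as an error. Calibration days
with zero admissions enter the regression as zeros; dropping them would
bias the intercept upward.

Because recorded admissions on busy days are censored by bed availability,
calibration against empirical records restricts the admission regression
to *low-occupancy days*: days at or below the unit's median midnight
census over the full calibration window. Ties with the median are
retained, so at least half the days always survive. This is a censoring
correction, and it is only appropriate when censoring is plausible: on
data generated without a capacity constraint the same filter selects
against days whose recent arrivals happened to be high and biases the
estimated demand downward. `calibrate_units()` therefore applies the
filter by default (the empirical use case) but exposes
`low_occupancy_filter = FALSE`, which the package's own parameter-recovery
tests use on unconstrained synthetic data. The filter also presumes the
median census sits well below capacity; in a congested unit whose median
is at capacity it cannot recover unconstrained demand.

**Discharges** are modelled per inpatient-day: for every midnight a
patient is present, the probability of discharge during the following day
is `plogis(intercept + weekday effect)`, with the weekday taken from the
*following* day — the decision made at midnight concerns the day that is
starting. A patient is at risk from the first midnight after admission, so
a stay admitted on day `d` and discharged on day `e` contributes at-risk
days `d+1 … e`, and day-case stays contribute none. No occupancy filter
applies here — discharges are not capacity-censored. Weekday is the sole
predictor: age, sex, residence, occupancy and stay-length-to-date are
intentionally excluded, since per-day discharge probabilities indexed by
weekday already reproduce the occupancy distribution, which is the
quantity of interest. The implied length-of-stay distribution is
geometric-like; it matches empirical *mean* stays but not their standard
deviation, a known and accepted simplification because occupancy depends
only on how many beds are filled, not on whose stay fills them. Complete
separation (a weekday with all-0 or all-1 outcomes, e.g. when every stay
lasts exactly one night) produces a warning and an effect with a very
large standard error rather than a failure.

Capacity is fixed: units are assumed never to add surge beds, and
financial or staffing constraints are out of scope.

## The Erlang loss model and its inverse

For an `n`-bed loss system offered a load of `ρ` beds (the occupancy the
unit would have with unlimited beds), the Erlang B formula gives the
blocked fraction

$$B(n, \rho) = \frac{\rho^n / n!}{\sum_{i=0}^{n} \rho^i / i!},
\qquad \text{occupancy} = \rho\,(1 - B(n, \rho)).$$

`erlang_loss()` uses the stable recurrence
`B₀ = 1, B_k = ρB_{k−1}/(k + ρB_{k−1})`: at `n = 72` the factorial form
overflows double precision, so the direct form survives only as the
small-`n` oracle in the test-suite. In capacity planning the *occupancy*
is what is observed and the load is unknown; since occupancy is strictly
increasing in `ρ`, `erlang_inverse_load()` grows a bracket geometrically
from `[occ, occ + 1]` until it overshoots and then bisects, terminating on
the occupancy residual (not the bracket width) at a tolerance of 1e-8
beds. Reported values are conventionally rounded to two decimals. An
observed occupancy at or above `n` is rejected: a finite-load loss system
never averages a full house. Non-integer bed counts are rejected too.

The Erlang model assumes a steady Poisson arrival rate. Real admission
rates vary by weekday and month, which concentrates demand and produces
*more* blocking than the steady-rate formula predicts; the test-suite
asserts this direction by comparing simulated turn-away fractions under
calendar-varying arrivals against the Erlang loss at the same average
load. The gap between the two estimates is the reason the simulation,
not the formula, is the primary instrument.

## Experiments

* `experiment_unconstrained()` runs a unit twice — capacity enforced and
  removed, on independent substreams — and reports the occupancy lost to
  the constraint. The unconstrained mean occupancy is the unit's load.
* `experiment_merge()` compares units operating as one pooled-capacity
  unit (arrivals per origin, origin-specific discharge coefficients,
  origin-fair random turn-away) against the sum of their individually
  constrained baselines. Pooling reduces blocking, so the increase is
  non-negative and grows with how loaded the members are.
* `find_removable_beds()` removes beds from the pooled capacity one at a
  time until the merged occupancy falls below a target service level
  (default: the sum of individual baselines). The sweep reuses the same
  run substreams at every capacity level — common random numbers — so the
  first failing level is not an artefact of fresh noise, and allows one
  Monte-Carlo standard error of slack in the comparison so the answer is
  not seed-dependent at the margin. Occupancy is monotone in capacity
  (verified under common random numbers in the tests), so the first
  failure ends the search.

## The synthetic-data generator

`make_scenario()` defines units with *known* coefficient sets and
`generate_records()` runs the engine in record-emitting mode, producing
admission records in the same schema as empirical files together with the
generating census trace. The presets mirror the size range of real units:
6 to 72 beds, mean stays of roughly 3 days (5 for the small unit), loads
from about 2 to 43 beds, with weekend and summer dips in arrivals and a
Friday discharge peak of the kind these units exhibit. Demographics (age
centred near 80, about two-thirds female) are filled from fixed marginals
for schema completeness only — they are never predictors. Discharge dates
falling beyond the simulated window are resolved by extending the
cool-down until every stay closes, so no record has a missing discharge
date; stays exceeding the 21-day cleaning threshold are possible under the
geometric stay law and are counted by the generator so tests can verify
the cleaner removes exactly those.

What passing tests on synthetic data do show: the engine's bookkeeping is
exact, calibration recovers the generating parameters at nominal coverage,
and the full generate→calibrate→simulate loop closes on occupancy. What
they cannot show: behaviour under features real data has and the model
lacks — over-dispersed arrivals, stay distributions with heavier tails
than geometric, secular trends, or units whose median occupancy sits at
capacity.

## Numerical and design choices

* Stays are cleaned with missing-date exclusion first, then the 21-day
  length-of-stay filter; the order is observationally irrelevant but fixed
  so cleaning logs are reproducible. Day-case (LOS 0) records are retained
  and contribute no occupancy.
* Dates are ISO-8601 text in files; the default calendar year starts
  2017-01-01 but is configurable.
* The test-suite sizes its simulations to the precision each check needs:
  the steady-state and capacity checks use the full 100 runs × 365 days
  design, parameter recovery uses 20 replicates of 5 unconstrained years,
  and ordering properties use 20–30 runs of 150–200 days, which keeps the
  whole suite under a minute while leaving every assertion several
  Monte-Carlo standard errors of headroom.
* Recovery checks compare at *combined* standard errors: run-level
  Monte-Carlo spread plus calibration sampling error propagated through
  occupancy = μ/p where the comparison involves re-fitted coefficients.

## Limitations

The model has no intra-day timing, no queueing of turned-away patients, no
occupancy-dependent admission or discharge behaviour, and fixed capacity.
Calibrated coefficients are unit-specific and year-specific; transferring
them across years assumes stable demand patterns. The Erlang triangulation
shares the loss-system assumptions but not the calendar structure, so it
systematically understates blocking — it is a cross-check, not a
substitute.
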